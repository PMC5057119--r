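#' Powell--Wetherall regression on prepared points
#'
#' Ordinary least squares of `y = mean_above - l_prime` on the cutoffs
#' `l_prime`. Under VBGF growth with steady state, constant recruitment and
#' exponential mortality Z, the mean length above a cutoff follows the
#' Beverton--Holt relation \eqn{\bar L = (Z L' + k L_\infty)/(Z + k)}, so
#' the fitted line has slope \eqn{b = -k/(Z+k) \in (-1, 0)} and
#' \eqn{L_\infty = -a/b}, \eqn{Z/k = -(1+b)/b}.
#'
#' @param l_prime Cutoff lengths, mm (at least 3 distinct values).
#' @param mean_above Mean length above each cutoff, mm.
#' @return An object of class `"powell_wetherall"`: list with the points,
#'   `a`, `b`, `l_inf_hat`, `z_over_k_hat`, `n_points`, `r_squared`.
#' @seealso [powell_wetherall()] for the version that starts from data.
#' @export
powell_wetherall_points <- function(l_prime, mean_above) {
  stopifnot(length(l_prime) == length(mean_above))
  if (length(unique(l_prime)) < 3L) {
    stop("degenerate fit: need at least 3 distinct cutoffs", call. = FALSE)
  }
  y <- mean_above - l_prime
  fit <- lm(y ~ l_prime)
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(b) || b >= 0 || b <= -1) {
    stop(sprintf(
      "degenerate fit: slope b = %.4f outside (-1, 0); population does not match the Beverton-Holt structure",
      b), call. = FALSE)
  }
  structure(
    list(l_prime = l_prime, mean_above = mean_above, y = y,
         a = a, b = b, l_inf_hat = -a / b, z_over_k_hat = -(1 + b) / b,
         n_points = length(l_prime),
         r_squared = r2),
    class = "powell_wetherall"
  )
}

#' Powell--Wetherall plot estimate of asymptotic length
#'
#' Builds the regression points from catch length data: one cutoff per bin
#' lower edge at or above `recruit_length` (the smallest fully recruited
#' size), keeping cutoffs whose tail holds at least `min_tail_count`
#' individuals, then calls [powell_wetherall_points()]. When raw lengths
#' are supplied the candidate cutoffs come from binning but the tail means
#' are computed from the raw lengths themselves (no discretisation loss);
#' with a pre-binned table bins contribute their midpoints. The fit is
#' invariant to rescaling all counts by a positive constant.
#'
#' @param x Raw lengths (numeric vector) or a `"length_frequency"` table.
#' @param recruit_length Smallest fully recruited length, mm (default 38).
#' @param bin_width Bin width used when `x` is raw lengths.
#' @param min_tail_count Minimum number of individuals above a cutoff for
#'   it to enter the regression (default 5).
#' @return A `"powell_wetherall"` object (see
#'   [powell_wetherall_points()]).
#' @examples
#' set.seed(1)
#' l <- sample_steady_state_lengths(5000, l_inf = 70.8, z_over_k = 2, l_c = 25)
#' powell_wetherall(l, recruit_length = 38)
#' @export
powell_wetherall <- function(x, recruit_length = 38, bin_width = 2,
                             min_tail_count = 5) {
  raw <- if (is.numeric(x) && !inherits(x, "length_frequency")) x
  lf <- as_length_frequency(x, bin_width = bin_width)
  stopifnot(recruit_length > 0)
  cutoffs <- lf$bin_lower[lf$bin_lower >= recruit_length]
  if (!length(cutoffs)) {
    stop("no length classes at or above `recruit_length`", call. = FALSE)
  }
  tail_n <- vapply(cutoffs, function(lp) {
    if (is.null(raw)) {
      w <- attr(lf, "bin_width")
      sum(lf$count[lf$bin_lower + w / 2 >= lp])
    } else {
      sum(raw >= lp)
    }
  }, numeric(1))
  cutoffs <- cutoffs[tail_n >= min_tail_count]
  if (length(cutoffs) < 3L) {
    stop("fewer than 3 usable cutoffs above `recruit_length`; lower `min_tail_count` or supply more data",
         call. = FALSE)
  }
  mean_above <- vapply(cutoffs, function(lp) {
    mean_length_above_cutoff(if (is.null(raw)) lf else raw, lp)
  }, numeric(1))
  out <- powell_wetherall_points(cutoffs, mean_above)
  out$recruit_length <- recruit_length
  out$min_tail_count <- min_tail_count
  out
}

#' @export
print.powell_wetherall <- function(x, ...) {
  cat("Powell-Wetherall fit\n")
  cat(sprintf("  points: %d (cutoffs %.1f-%.1f mm)\n", x$n_points,
              min(x$l_prime), max(x$l_prime)))
  cat(sprintf("  a = %.3f mm, b = %.4f, R^2 = %.3f\n", x$a, x$b, x$r_squared))
  cat(sprintf("  L_inf = %.2f mm, Z/k = %.3f\n", x$l_inf_hat, x$z_over_k_hat))
  invisible(x)
}

#' @export
plot.powell_wetherall <- function(x, ...) {
  plot(x$l_prime, x$y, xlab = "Cutoff length L' (mm)",
       ylab = expression(bar(L) - "L'" ~ (mm)),
       main = "Powell-Wetherall plot", ...)
  abline(a = x$a, b = x$b)
  invisible(x)
}
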