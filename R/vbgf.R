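#' von Bertalanffy growth envelope
#'
#' Length at time `t` for an individual of initial length `l0` growing along
#' the von Bertalanffy growth function (VBGF),
#' \deqn{L(t) = L_\infty - (L_\infty - L_0) e^{-k t}.}
#' For moulting crustaceans the VBGF describes the smooth envelope that
#' stepped (moult-wise) growth averages out to over a cohort.
#'
#' @param l0 Initial carapace length, mm. Must satisfy `0 <= l0 < l_inf`.
#' @param t Elapsed time in years, `>= 0`. Vectorised.
#' @param l_inf Asymptotic carapace length, mm.
#' @param k Growth constant, per year (`> 0`).
#' @return Length in mm, same shape as `t` (or `l0` if `t` is scalar).
#' @examples
#' vbgf_envelope(32, 1, l_inf = 70.8, k = 0.161)
#' @export
vbgf_envelope <- function(l0, t, l_inf, k) {
  stopifnot(is.numeric(l0), is.numeric(t), is_scalar_number(l_inf),
            is_scalar_number(k))
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (any(l0 < 0) || any(l0 >= l_inf)) {
    stop("`l0` must lie in [0, l_inf)", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  l_inf - (l_inf - l0) * exp(-k * t)
}

#' Stepped (moult-wise) growth trajectory
#'
#' Carapace length is piecewise constant between moults; at each moult the
#' individual jumps onto the VBGF envelope anchored at its release length,
#' evaluated at the moult time. The increment accumulated over any interval
#' therefore equals the envelope increment up to the last moult in the
#' interval, and the trajectory never exceeds the envelope (equality exactly
#' at moult times).
#'
#' @param release_cl Carapace length at release, mm.
#' @param moult_days Moult times in days since release, sorted, `>= 0`.
#'   Times beyond `recapture_day` are retained in the schedule but do not
#'   contribute to the realised size at recapture.
#' @param l_inf,k VBGF parameters (mm, per year).
#' @param recapture_day Day of recapture (days since release). Defaults to
#'   the last moult time (or 0 if none).
#' @param sex Optional sex label carried through for bookkeeping.
#' @return An object of class `"moult_trajectory"`: a list with
#'   `release_cl`, `moult_days`, `post_moult_cls`, `recapture_day`,
#'   `final_cl` and `sex`.
#' @seealso [vbgf_envelope()], [cl_at_day()]
#' @export
stepped_growth <- function(release_cl, moult_days, l_inf, k,
                           recapture_day = NULL, sex = NA_character_) {
  stopifnot(is_scalar_number(release_cl), is.numeric(moult_days))
  if (is.unsorted(moult_days)) stop("`moult_days` must be sorted", call. = FALSE)
  if (any(moult_days < 0)) stop("`moult_days` must be >= 0", call. = FALSE)
  if (is.null(recapture_day)) {
    recapture_day <- if (length(moult_days)) max(moult_days) else 0
  }
  realised <- moult_days[moult_days <= recapture_day]
  post_cls <- vbgf_envelope(release_cl, moult_days / 365.25, l_inf, k)
  final_cl <- if (length(realised)) {
    vbgf_envelope(release_cl, max(realised) / 365.25, l_inf, k)
  } else {
    release_cl
  }
  structure(
    list(release_cl = release_cl, moult_days = moult_days,
         post_moult_cls = post_cls, recapture_day = recapture_day,
         final_cl = final_cl, sex = sex, l_inf = l_inf, k = k),
    class = "moult_trajectory"
  )
}

#' Evaluate a stepped trajectory at a given day
#'
#' @param traj A `"moult_trajectory"` from [stepped_growth()].
#' @param day Days since release (vectorised).
#' @return Carapace length at `day` (piecewise constant).
#' @export
cl_at_day <- function(traj, day) {
  stopifnot(inherits(traj, "moult_trajectory"))
  vapply(day, function(d) {
    past <- traj$moult_days[traj$moult_days <= d]
    if (length(past)) {
      vbgf_envelope(traj$release_cl, max(past) / 365.25, traj$l_inf, traj$k)
    } else {
      traj$release_cl
    }
  }, numeric(1))
}

#' @export
print.moult_trajectory <- function(x, ...) {
  cat("Stepped growth trajectory\n")
  cat(sprintf("  release CL: %.1f mm;  %d moult(s);  recapture day %d\n",
              x$release_cl, length(x$moult_days), round(x$recapture_day)))
  cat(sprintf("  final CL: %.2f mm (envelope L_inf = %.1f, k = %.3f)\n",
              x$final_cl, x$l_inf, x$k))
  invisible(x)
}
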