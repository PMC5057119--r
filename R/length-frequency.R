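#' Bin raw lengths into a length-frequency table
#'
#' Left-closed, right-open bins `[lower, lower + bin_width)` anchored at
#' `origin`. Total count is conserved.
#'
#' @param x Numeric vector of lengths (mm), or an existing
#'   length-frequency data frame (returned unchanged).
#' @param bin_width Bin width, mm (default 2, the conventional carapace
#'   length class width).
#' @param origin Alignment origin for bin edges (default 0).
#' @return Data frame of class `"length_frequency"` with columns
#'   `bin_lower` and `count`, and attribute `bin_width`.
#' @examples
#' as_length_frequency(c(38.0, 39.9, 40.0))
#' @export
as_length_frequency <- function(x, bin_width = 2, origin = 0) {
  if (inherits(x, "length_frequency")) return(x)
  stopifnot(is.numeric(x), bin_width > 0)
  if (!length(x)) {
    out <- data.frame(bin_lower = numeric(0), count = integer(0))
  } else {
    lower <- origin + floor((x - origin) / bin_width) * bin_width
    tab <- table(lower)
    out <- data.frame(bin_lower = as.numeric(names(tab)),
                      count = as.integer(tab))
    out <- out[order(out$bin_lower), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, bin_width = bin_width, class = c("length_frequency",
                                                  "data.frame"))
}

#' Construct a length-frequency table from pre-binned counts
#'
#' @param bin_lower Lower bin edges, mm.
#' @param count Counts per bin.
#' @param bin_width Bin width, mm.
#' @return A `"length_frequency"` data frame.
#' @export
length_frequency <- function(bin_lower, count, bin_width = 2) {
  stopifnot(length(bin_lower) == length(count), all(count >= 0),
            bin_width > 0)
  ord <- order(bin_lower)
  structure(data.frame(bin_lower = as.numeric(bin_lower)[ord],
                       count = as.numeric(count)[ord]),
            bin_width = bin_width,
            class = c("length_frequency", "data.frame"))
}

#' Mean length above a cutoff
#'
#' Count-weighted mean of all lengths at or above `l_prime`. For binned
#' tables, bins are represented by their midpoints and a bin contributes
#' when its midpoint is `>= l_prime` (so a cutoff at a bin's lower edge
#' includes that bin).
#'
#' @param x Raw lengths (numeric) or a `"length_frequency"` table.
#' @param l_prime Cutoff length, mm.
#' @return Mean length (mm) of the tail at or above the cutoff.
#' @export
mean_length_above_cutoff <- function(x, l_prime) {
  if (inherits(x, "length_frequency")) {
    w <- attr(x, "bin_width")
    mid <- x$bin_lower + w / 2
    keep <- mid >= l_prime & x$count > 0
    if (!any(keep)) stop("no individuals at or above the cutoff", call. = FALSE)
    sum(mid[keep] * x$count[keep]) / sum(x$count[keep])
  } else {
    stopifnot(is.numeric(x))
    tail_x <- x[x >= l_prime]
    if (!length(tail_x)) stop("no individuals at or above the cutoff",
                              call. = FALSE)
    mean(tail_x)
  }
}
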