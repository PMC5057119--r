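#' Histogram of growth increments
#'
#' Left-closed bins of width `bin_width` starting at 0; counts sum to the
#' number of records. Used to read moult frequency off the increment
#' distribution: with roughly half the males moulting twice a year the male
#' histogram is bimodal, while females (one moult) are unimodal.
#'
#' @param dcl Numeric vector of increments, mm CL (negative values are
#'   binned below zero and reported too).
#' @param bin_width Bin width, mm (default 1).
#' @return Data frame `bin_lower`, `count` with attribute `bin_width`.
#' @export
increment_histogram <- function(dcl, bin_width = 1) {
  stopifnot(bin_width > 0)
  as_length_frequency(dcl, bin_width = bin_width, origin = 0)
}

#' Count strict local maxima of a histogram
#'
#' Helper for mode counting on binned counts (ties broken by plateau
#' collapse). A bin is a mode when its count exceeds both neighbours'
#' (edge bins compare against their single neighbour).
#'
#' @param counts Integer vector of bin counts.
#' @return Number of local maxima.
#' @export
count_modes <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2L) return(length(counts))
  # collapse plateaus so runs of equal counts act as one candidate
  r <- rle(counts)$values
  n <- length(r)
  if (n == 1L) return(1L)
  up <- c(TRUE, r[-1] > r[-n])
  down <- c(r[-n] > r[-1], TRUE)
  sum(up & down & r > 0)
}

#' Default moult-mode increment windows
#'
#' Increment windows separating one from two (and three or more) moults:
#' increments below 4.49 mm mark a single moult, 5.50--8.49 mm two moults,
#' above 8.49 mm three or more; the gap 4.49--5.50 mm is left unclassified
#' (and excluded from two-group comparisons).
#'
#' @param mode1_max Upper (exclusive) bound of the one-moult window, mm.
#' @param mode2_range `(min, max)` of the two-moult window, mm (inclusive).
#' @return List of class `"moult_mode_boundaries"`.
#' @export
moult_mode_boundaries <- function(mode1_max = 4.49,
                                  mode2_range = c(5.50, 8.49)) {
  stopifnot(mode1_max > 0, length(mode2_range) == 2L,
            mode2_range[1] >= mode1_max, mode2_range[2] > mode2_range[1])
  structure(list(mode1_max = mode1_max, mode2_range = as.numeric(mode2_range)),
            class = "moult_mode_boundaries")
}

#' Classify increments into moult-frequency modes
#'
#' Each positive increment gets exactly one label: `"1 moult"` when
#' `0 < dcl < mode1_max`, `"2 moults"` inside `mode2_range` (inclusive),
#' `">=3 moults"` above it, `"unclassified"` in the gap between the
#' windows (or at/below zero).
#'
#' @param dcl Increments, mm CL.
#' @param boundaries A [moult_mode_boundaries()] object.
#' @return List with `labels` (factor, same length as `dcl`) and `counts`
#'   (named integer vector over the four labels).
#' @examples
#' classify_moult_modes(c(3, 6, 5, 9))$labels
#' @export
classify_moult_modes <- function(dcl, boundaries = moult_mode_boundaries()) {
  stopifnot(inherits(boundaries, "moult_mode_boundaries"))
  lv <- c("1 moult", "2 moults", ">=3 moults", "unclassified")
  lab <- rep("unclassified", length(dcl))
  lab[dcl > 0 & dcl < boundaries$mode1_max] <- "1 moult"
  lab[dcl >= boundaries$mode2_range[1] &
        dcl <= boundaries$mode2_range[2]] <- "2 moults"
  lab[dcl > boundaries$mode2_range[2]] <- ">=3 moults"
  labels <- factor(lab, levels = lv)
  list(labels = labels, counts = table(labels))
}

#' Compare starting sizes of one- vs two-moult individuals
#'
#' Two-sample t test of release carapace length between individuals
#' classified as single and double moulters. A positive statistic means
#' one-moulters start larger, the pattern expected when small individuals
#' moult more often. Pooled-variance by default (`var_equal = TRUE`, the
#' convention of classical stats packages); Welch available.
#'
#' @param size_one_moult,size_two_moult Release CL (mm) in each group,
#'   both of length >= 2.
#' @param var_equal Use the pooled-variance t test (default) or Welch.
#' @return List with `t`, `df`, `p_value`, `mean_one`, `mean_two` and the
#'   underlying `htest`.
#' @export
compare_mode_starting_sizes <- function(size_one_moult, size_two_moult,
                                        var_equal = TRUE) {
  stopifnot(length(size_one_moult) >= 2L, length(size_two_moult) >= 2L)
  ht <- t.test(size_one_moult, size_two_moult, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_one = mean(size_one_moult), mean_two = mean(size_two_moult),
       htest = ht)
}

#' Mann--Whitney comparison of wild vs captive increments
#'
#' Reports medians and ranges per group and the Mann--Whitney U statistic
#' with a two-sided p value (normal approximation with mid-ranks for
#' ties, no continuity correction, so identical samples give p = 1
#' exactly). `U` is reported in the min-U convention,
#' `min(U_wild, n_wild * n_captive - U_wild)`, matching classical
#' statistical package output; set `convention = "first"` for the U of the
#' first sample.
#'
#' @param wild,captive Increment samples, mm CL (nonempty).
#' @param convention `"min"` (default) or `"first"`.
#' @return List with `U`, `p_value`, `n_wild`, `n_captive`,
#'   `median_wild`, `median_captive`, `range_wild`, `range_captive`.
#' @export
wild_vs_captive_test <- function(wild, captive, convention = c("min", "first")) {
  convention <- match.arg(convention)
  stopifnot(length(wild) >= 1L, length(captive) >= 1L)
  ht <- suppressWarnings(wilcox.test(wild, captive, exact = FALSE,
                                     correct = FALSE))
  u_first <- unname(ht$statistic)
  u <- if (convention == "min") {
    min(u_first, length(wild) * length(captive) - u_first)
  } else {
    u_first
  }
  list(U = u, p_value = ht$p.value,
       n_wild = length(wild), n_captive = length(captive),
       median_wild = median(wild), median_captive = median(captive),
       range_wild = range(wild), range_captive = range(captive))
}

#' Spearman correlation between starting size and increment
#'
#' Rank correlation (mid-ranks for ties) of release CL against growth
#' increment; a negative coefficient indicates lower growth in larger
#' individuals, the pattern the VBGF assumes.
#'
#' @param l1 Release CL, mm (n >= 3).
#' @param dcl Increments, mm CL.
#' @return List with `rho`, `p_value`, `n`.
#' @export
size_growth_correlation <- function(l1, dcl) {
  stopifnot(length(l1) == length(dcl), length(l1) >= 3L)
  ht <- suppressWarnings(cor.test(l1, dcl, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(l1))
}

#' Detect moults in a captive monthly length series
#'
#' A moult is scored between consecutive observations when the length
#' increase exceeds `threshold` (0.5 mm) and is sustained: every later
#' observation stays more than `threshold` above the pre-moult length.
#' Externally flagged events (shell fragments, soft shell) are accepted as
#' moults regardless of the size rule. Gaps in the observation calendar are
#' allowed; a series with fewer than two observations yields no events and
#' a warning.
#'
#' @param cl Chronological CL observations, mm.
#' @param dates Optional observation dates (same length).
#' @param flags Optional logical vector: external moult evidence at each
#'   observation.
#' @param threshold Sustained-increase threshold, mm (default 0.5,
#'   exclusive).
#' @return Data frame with one row per event: `step` (index of the
#'   pre-moult observation), `dcl`, `source` (`"size"` or `"flag"`), and
#'   `date` when dates are supplied.
#' @examples
#' detect_captive_moults(c(30.0, 30.0, 31.2, 31.2))
#' @export
detect_captive_moults <- function(cl, dates = NULL, flags = NULL,
                                  threshold = 0.5) {
  n <- length(cl)
  if (n < 2L) {
    warning("fewer than 2 observations: no moults detectable", call. = FALSE)
    return(data.frame(step = integer(0), dcl = numeric(0),
                      source = character(0)))
  }
  if (!is.null(flags)) stopifnot(length(flags) == n)
  if (!is.null(dates)) stopifnot(length(dates) == n)
  steps <- integer(0); dcls <- numeric(0); src <- character(0)
  for (i in seq_len(n - 1L)) {
    jump <- cl[i + 1L] - cl[i]
    sustained <- jump > threshold && all(cl[(i + 1L):n] > cl[i] + threshold)
    flagged <- !is.null(flags) && isTRUE(flags[i + 1L])
    if (sustained || flagged) {
      steps <- c(steps, i)
      dcls <- c(dcls, jump)
      src <- c(src, if (sustained) "size" else "flag")
    }
  }
  out <- data.frame(step = steps, dcl = dcls, source = src,
                    stringsAsFactors = FALSE)
  if (!is.null(dates) && nrow(out)) out$date <- dates[out$step + 1L]
  out
}
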