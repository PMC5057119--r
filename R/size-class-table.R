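#' Size-class growth increment table
#'
#' Tabulates growth by release size class, per sex: number recaptured,
#' mean increment in mm CL, mm TL and g (each with the standard error of
#' the mean), in the style of published tag-recapture summaries. Classes
#' are left-closed `[lower, upper)` on release CL; records outside all
#' classes are excluded with a message. The SE of a single-record class is
#' reported as 0. The count-weighted mean of the class means equals the
#' overall mean increment exactly (before any rounding).
#'
#' @param records Filtered increment records (see [increment_records()]).
#' @param class_edges Sorted class edges, mm (default `seq(26, 40, 2)`).
#' @param conversions A [conversion_params()] object for the TL and weight
#'   columns.
#' @return Data frame of class `"size_class_table"` with columns `sex`,
#'   `class_lower`, `class_upper`, `n`, `mean_dcl`, `se_dcl`, `mean_dtl`,
#'   `se_dtl`, `mean_dw`, `se_dw`; the per-sex overall summary is in
#'   `attr(, "overall")`.
#' @export
build_size_class_table <- function(records, class_edges = seq(26, 40, 2),
                                   conversions = conversion_params()) {
  if (!all(c("dl", "l1") %in% names(records))) {
    records <- increment_records(records)
  }
  stopifnot(!is.unsorted(class_edges), length(class_edges) >= 2L)
  lower <- class_edges[-length(class_edges)]
  upper <- class_edges[-1]
  cls <- findInterval(records$l1, class_edges)
  outside <- cls == 0L | records$l1 >= class_edges[length(class_edges)]
  if (any(outside)) {
    message(sum(outside), " record(s) outside the class range excluded")
    records <- records[!outside, , drop = FALSE]
    cls <- cls[!outside]
  }
  se0 <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  rows <- list(); overall <- list()
  for (s in sort(unique(records$sex))) {
    in_sex <- records$sex == s
    dtl <- dcl_to_dtl(records$dl, conversions)
    dw <- dweight(records$l1, records$l2, conversions)
    for (j in seq_along(lower)) {
      idx <- in_sex & cls == j
      n <- sum(idx)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, class_lower = lower[j], class_upper = upper[j], n = n,
        mean_dcl = if (n) mean(records$dl[idx]) else NA_real_,
        se_dcl = if (n) se0(records$dl[idx]) else NA_real_,
        mean_dtl = if (n) mean(dtl[idx]) else NA_real_,
        se_dtl = if (n) se0(dtl[idx]) else NA_real_,
        mean_dw = if (n) mean(dw[idx]) else NA_real_,
        se_dw = if (n) se0(dw[idx]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    overall[[length(overall) + 1L]] <- data.frame(
      sex = s, n = sum(in_sex),
      mean_dcl = mean(records$dl[in_sex]), se_dcl = se0(records$dl[in_sex]),
      mean_dtl = mean(dtl[in_sex]), se_dtl = se0(dtl[in_sex]),
      mean_dw = mean(dw[in_sex]), se_dw = se0(dw[in_sex]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, overall = do.call(rbind, overall),
            class = c("size_class_table", "data.frame"))
}

#' @export
print.size_class_table <- function(x, digits = 1, ...) {
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1)) &
    !names(disp) %in% c("class_lower", "class_upper", "n")
  disp[num] <- lapply(disp[num], round, digits = digits)
  print(disp, row.names = FALSE)
  ov <- attr(x, "overall")
  if (!is.null(ov)) {
    cat("\nOverall (count-weighted):\n")
    ovn <- vapply(ov, is.numeric, logical(1)) & names(ov) != "n"
    ov[ovn] <- lapply(ov[ovn], round, digits = digits)
    print(ov, row.names = FALSE)
  }
  invisible(x)
}

#' Count-weighted overall mean from class summaries
#'
#' `sum(n * means) / sum(n)` over size classes -- the arithmetic that links
#' per-class means back to the overall mean increment.
#'
#' @param n Class counts.
#' @param means Class means (same length; classes with `n = 0` may carry
#'   `NA` means).
#' @return The weighted mean.
#' @export
overall_mean_from_classes <- function(n, means) {
  stopifnot(length(n) == length(means))
  keep <- n > 0
  sum(n[keep] * means[keep]) / sum(n[keep])
}

#' Recapture rate as a percentage
#'
#' @param n_recaptured Number (or numbers, summed) of recaptured
#'   individuals.
#' @param n_released Number released.
#' @return Percentage, unrounded.
#' @export
recapture_rate <- function(n_recaptured, n_released) {
  stopifnot(n_released > 0, all(n_recaptured >= 0))
  100 * sum(n_recaptured) / n_released
}
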