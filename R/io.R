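#' Read tag-recapture records from CSV
#'
#' Expects columns `tag_id`, `sex`, `release_date`, `release_cl_mm`,
#' `recapture_date`, `recapture_cl_mm` (ISO-8601 dates, mm CL). Rows that
#' cannot be used -- unparseable dates or lengths, or a recapture date not
#' after release -- are collected into `attr(, "rejected")` with a reason,
#' never silently dropped. A missing column is a schema error naming the
#' column.
#'
#' @param path CSV file path.
#' @return Data frame of valid tag records (dates as `Date`), with
#'   attribute `rejected` (data frame with a `reason` column).
#' @export
read_tag_records <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "sex", "release_date", "release_cl_mm",
            "recapture_date", "recapture_cl_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("tag record file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rel <- as.Date(as.character(raw$release_date), format = "%Y-%m-%d")
  rec <- as.Date(as.character(raw$recapture_date), format = "%Y-%m-%d")
  l1 <- suppressWarnings(as.numeric(raw$release_cl_mm))
  l2 <- suppressWarnings(as.numeric(raw$recapture_cl_mm))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(rel) | is.na(rec)] <- "unparseable date"
  reason[is.na(reason) & (is.na(l1) | is.na(l2))] <- "unparseable length"
  reason[is.na(reason) & rec <= rel] <- "recapture date not after release"
  ok <- is.na(reason)
  out <- data.frame(tag_id = as.character(raw$tag_id[ok]),
                    sex = as.character(raw$sex[ok]),
                    release_date = rel[ok], release_cl_mm = l1[ok],
                    recapture_date = rec[ok], recapture_cl_mm = l2[ok],
                    stringsAsFactors = FALSE)
  rejected <- raw[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  attr(out, "rejected") <- rejected
  out
}

#' Write tag-recapture records to CSV
#'
#' Inverse of [read_tag_records()]: ISO-8601 dates, mm CL columns.
#'
#' @param tags Tag record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_records <- function(tags, path) {
  out <- tags[c("tag_id", "sex", "release_date", "release_cl_mm",
                "recapture_date", "recapture_cl_mm")]
  out$release_date <- format(as.Date(out$release_date))
  out$recapture_date <- format(as.Date(out$recapture_date))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read catch length data from CSV
#'
#' Accepts either raw per-individual lengths (columns `sex`, optional
#' `month`, `cl_mm`) or pre-binned counts (columns `sex`, optional
#' `month`, `cl_bin_lower_mm`, `count`). Raw lengths are binned with
#' left-closed edges of width `bin_width`; pre-binned counts pass through
#' unchanged. Total count is conserved either way.
#'
#' @param path CSV file path.
#' @param bin_width Bin width, mm, used for raw lengths (default 2).
#' @return Data frame with columns `sex`, `month` (NA when absent),
#'   `bin_lower`, `count`; attribute `bin_width`.
#' @export
read_length_frequency <- function(path, bin_width = 2) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sex" %in% names(raw)) {
    stop("length-frequency file is missing column(s): sex", call. = FALSE)
  }
  month <- if ("month" %in% names(raw)) raw$month else NA_integer_
  if (all(c("cl_bin_lower_mm", "count") %in% names(raw))) {
    out <- data.frame(sex = raw$sex, month = month,
                      bin_lower = as.numeric(raw$cl_bin_lower_mm),
                      count = as.numeric(raw$count),
                      stringsAsFactors = FALSE)
  } else if ("cl_mm" %in% names(raw)) {
    grp <- if (all(is.na(month))) raw$sex else paste(raw$sex, month)
    pieces <- split(seq_len(nrow(raw)), grp)
    out <- do.call(rbind, lapply(pieces, function(idx) {
      lf <- as_length_frequency(as.numeric(raw$cl_mm[idx]),
                                bin_width = bin_width)
      data.frame(sex = raw$sex[idx][1],
                 month = if (all(is.na(month))) NA else month[idx][1],
                 bin_lower = lf$bin_lower, count = lf$count,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  } else {
    stop("length-frequency file needs either `cl_mm` or `cl_bin_lower_mm` + `count`",
         call. = FALSE)
  }
  attr(out, "bin_width") <- bin_width
  out
}

#' Write a length-frequency table to CSV
#'
#' @param lf Data frame with `sex`, `month`, `bin_lower`, `count` (as from
#'   [read_length_frequency()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_frequency <- function(lf, path) {
  out <- data.frame(sex = lf$sex, month = lf$month,
                    cl_bin_lower_mm = lf$bin_lower, count = lf$count)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a multi-group length-frequency table
#'
#' Aggregates counts over months (and optionally restricts to one sex),
#' returning a single `"length_frequency"` usable by
#' [powell_wetherall()].
#'
#' @param lf Data frame from [read_length_frequency()] (or with the same
#'   columns).
#' @param sex Optional sex to keep (`"M"` or `"F"`).
#' @param months Optional months to keep.
#' @return A `"length_frequency"` data frame.
#' @export
collapse_length_frequency <- function(lf, sex = NULL, months = NULL) {
  keep <- rep(TRUE, nrow(lf))
  if (!is.null(sex)) keep <- keep & lf$sex %in% sex
  if (!is.null(months)) keep <- keep & lf$month %in% months
  sub <- lf[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no rows left after subsetting", call. = FALSE)
  agg <- tapply(sub$count, sub$bin_lower, sum)
  length_frequency(as.numeric(names(agg)), as.numeric(agg),
                   bin_width = attr(lf, "bin_width") %||% 2)
}

#' Read a captive monitoring series from CSV
#'
#' Columns `tag_id`, `obs_date` (ISO-8601), `cl_mm` and optionally
#' `moult_flag` (logical: shell fragments / soft shell observed).
#'
#' @param path CSV file path.
#' @return Data frame sorted by `tag_id` then `obs_date`.
#' @export
read_captive_series <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "obs_date", "cl_mm")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("captive series file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw$obs_date <- as.Date(raw$obs_date)
  if (!"moult_flag" %in% names(raw)) raw$moult_flag <- FALSE
  raw$moult_flag <- as.logical(raw$moult_flag)
  raw[order(raw$tag_id, raw$obs_date), , drop = FALSE]
}

#' Published study inputs shipped with the package
#'
#' Small reference tables transcribed from the tag-recapture study this
#' package's methods reproduce: release/recapture counts and the per-sex
#' size-class increment and weight tables for the one-year and two-year
#' liberty periods. Used by the worked examples and the acceptance script
#' as inputs, the way a user would supply their own field summaries.
#'
#' @param year Liberty period: 1 (about 344 days) or 2 (about 660 days).
#' @return `nephrops_increment_table()`: data frame with `sex`,
#'   `class_lower`, `class_upper`, `n`, `mean_dcl`, `se_dcl` and (year 1
#'   only) `mean_dtl`, `se_dtl`, plus `mean_dw`, `se_dw`.
#'   `nephrops_study_counts()`: named list with `n_released`,
#'   `n_recaptured_y1`, `n_recaptured_y2`.
#' @export
nephrops_increment_table <- function(year = 1) {
  stopifnot(year %in% c(1, 2))
  f <- system.file("extdata",
                   sprintf("increment_table_y%d.csv", year),
                   package = "nephrogrowth", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname nephrops_increment_table
#' @export
nephrops_study_counts <- function() {
  f <- system.file("extdata", "tagging_summary.csv",
                   package = "nephrogrowth", mustWork = TRUE)
  x <- read.csv(f, stringsAsFactors = FALSE)
  as.list(setNames(x$count, x$quantity))
}
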