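#' Build increment records from tag-recapture data
#'
#' Derives, per individual, the quantities used on a Gulland--Holt plot:
#' release length `l1`, recapture length `l2`, days at liberty `dt`,
#' increment `dl = l2 - l1`, mean length at liberty `lbar = (l1 + l2)/2`
#' and annualised growth rate `rate = dl / (dt/365.25)` (mm per year).
#'
#' @param tags Data frame of tag records with columns `tag_id`, `sex`,
#'   `release_cl_mm`, `recapture_cl_mm` and either `release_date` +
#'   `recapture_date` or a precomputed `dt_days`.
#' @return Data frame with columns `tag_id`, `sex`, `l1`, `l2`, `dt`,
#'   `dl`, `lbar`, `rate`.
#' @export
increment_records <- function(tags) {
  stopifnot(is.data.frame(tags))
  need <- c("tag_id", "sex", "release_cl_mm", "recapture_cl_mm")
  miss <- setdiff(need, names(tags))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if ("dt_days" %in% names(tags)) {
    dt <- as.numeric(tags$dt_days)
  } else if (all(c("release_date", "recapture_date") %in% names(tags))) {
    dt <- as.numeric(as.Date(tags$recapture_date) - as.Date(tags$release_date))
  } else {
    stop("missing column(s): release_date/recapture_date (or dt_days)",
         call. = FALSE)
  }
  l1 <- as.numeric(tags$release_cl_mm)
  l2 <- as.numeric(tags$recapture_cl_mm)
  data.frame(tag_id = as.character(tags$tag_id), sex = as.character(tags$sex),
             l1 = l1, l2 = l2, dt = dt, dl = l2 - l1, lbar = (l1 + l2) / 2,
             rate = (l2 - l1) / (dt / 365.25), stringsAsFactors = FALSE)
}

#' Filter increment records before growth estimation
#'
#' Drops, with an audited reason per record: unreadable tags (missing or
#' empty `tag_id`), records with missing lengths or liberty, non-positive
#' liberty, and zero-or-negative growth (`dl <= min_dl`). Zero/negative
#' growth typically marks individuals recaptured before their first moult
#' (or measurement error) and is excluded from Gulland--Holt fitting.
#'
#' @param records Increment records from [increment_records()] (a tag
#'   record data frame is converted automatically).
#' @param min_dl Exclusive lower bound on increments to keep (default 0:
#'   keep `dl > 0`).
#' @return List of class `"increment_filter"` with `kept` (data frame),
#'   `dropped` (data frame with a `reason` column) and `audit` (named
#'   integer counts per reason).
#' @export
filter_increments <- function(records, min_dl = 0) {
  if (!all(c("dl", "lbar", "rate") %in% names(records))) {
    records <- increment_records(records)
  }
  reason <- rep(NA_character_, nrow(records))
  bad_id <- is.na(records$tag_id) | records$tag_id == ""
  reason[bad_id] <- "unreadable tag"
  bad_len <- is.na(records$l1) | is.na(records$l2)
  reason[is.na(reason) & bad_len] <- "missing length"
  bad_dt <- is.na(records$dt) | records$dt <= 0
  reason[is.na(reason) & bad_dt] <- "non-positive liberty"
  nonpos <- !is.na(records$dl) & records$dl <= min_dl
  reason[is.na(reason) & nonpos] <- "non-positive growth"
  keep <- is.na(reason)
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  audit <- if (nrow(dropped)) table(dropped$reason) else table(character(0))
  structure(list(kept = records[keep, , drop = FALSE],
                 dropped = dropped,
                 audit = vapply(as.list(audit), as.integer, integer(1))),
            class = "increment_filter")
}

#' @export
print.increment_filter <- function(x, ...) {
  cat(sprintf("Increment filter: %d kept, %d dropped\n",
              nrow(x$kept), nrow(x$dropped)))
  if (length(x$audit)) {
    for (r in names(x$audit)) cat(sprintf("  %-22s %d\n", r, x$audit[[r]]))
  }
  invisible(x)
}
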