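#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs: either file paths to field
#' data or a [sim_config()] to generate synthetic data, plus the analysis
#' settings. All randomness flows from the single seed.
#'
#' @param tags_y1,tags_y2 Paths to tag-record CSVs for the first and
#'   (optionally) second liberty period, or data frames; `NULL` to skip.
#' @param catch Path to a catch length CSV, or a data frame with `sex` and
#'   `cl_mm` columns; `NULL` to skip the Powell--Wetherall step.
#' @param captive Path to a captive-series CSV or a data frame; `NULL` to
#'   skip captive moult detection.
#' @param sim A [sim_config()]; when given, tag, catch and captive data are
#'   simulated instead of read (`n_tags_y1`, `n_tags_y2`, `n_catch` control
#'   sizes; `n_tags_y2 = 0` skips year 2).
#' @param n_tags_y1,n_tags_y2,n_catch Simulated sample sizes.
#' @param recruit_length Smallest fully recruited length for the
#'   Powell--Wetherall cutoffs, mm (default 38).
#' @param bin_width Length-frequency bin width, mm (default 2).
#' @param min_tail_count Minimum tail count per Powell--Wetherall cutoff.
#' @param class_edges Size-class edges for the increment table.
#' @param conversions A [conversion_params()].
#' @param boundaries A [moult_mode_boundaries()].
#' @param out_dir Output directory for CSV/report files; `NULL` for none.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(tags_y1 = NULL, tags_y2 = NULL, catch = NULL,
                       captive = NULL, sim = NULL,
                       n_tags_y1 = 207, n_tags_y2 = 0, n_catch = 4252,
                       recruit_length = 38, bin_width = 2,
                       min_tail_count = 5, class_edges = seq(26, 40, 2),
                       conversions = conversion_params(),
                       boundaries = moult_mode_boundaries(),
                       out_dir = NULL) {
  if (is.null(sim) && is.null(tags_y1)) {
    stop("supply either tag data (`tags_y1`) or a simulation config (`sim`)",
         call. = FALSE)
  }
  stopifnot(recruit_length > 0, bin_width > 0)
  structure(list(tags_y1 = tags_y1, tags_y2 = tags_y2, catch = catch,
                 captive = captive, sim = sim, n_tags_y1 = n_tags_y1,
                 n_tags_y2 = n_tags_y2, n_catch = n_catch,
                 recruit_length = recruit_length, bin_width = bin_width,
                 min_tail_count = min_tail_count, class_edges = class_edges,
                 conversions = conversions, boundaries = boundaries,
                 out_dir = out_dir),
            class = "run_config")
}

resolve_tags <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x else read_tag_records(x)
}

#' Run the full growth-estimation pipeline
#'
#' Orchestrates the analysis in its natural order: filter increments (with
#' a per-reason drop audit), size-class increment table, increment
#' histograms and moult-mode classification with the starting-size
#' comparison, Powell--Wetherall estimation of the per-sex asymptotic
#' length from the catch sample, forced Gulland--Holt estimation of k at
#' that asymptotic length, and pooling over liberty periods when a second
#' year of recaptures is available. Deterministic given the configuration
#' (simulation seeds live in the [sim_config()]).
#'
#' @param config A [run_config()].
#' @return A list report: `tags`, `filter` (per year), `table`,
#'   `histograms`, `modes`, `mode_size_test`, `powell_wetherall`,
#'   `gulland_holt` (per sex), `captive_moults`, `warnings`. Written to
#'   `out_dir` as CSV and a key-value report when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(warnings = character(0))
  warn <- function(msg) report$warnings <<- c(report$warnings, msg)

  if (!is.null(config$sim)) {
    tags1 <- simulate_tag_recapture(config$sim, config$n_tags_y1)
    tags2 <- if (config$n_tags_y2 > 0) {
      cfg2 <- config$sim
      cfg2$liberty_days_mean <- 2 * cfg2$liberty_days_mean
      cfg2$seed <- cfg2$seed + 10L
      validate_sim_config(cfg2)
      simulate_tag_recapture(cfg2, config$n_tags_y2)
    }
    catch <- simulate_catch_sample(config$sim, config$n_catch)
    captive <- simulate_captive_series(config$sim)
  } else {
    tags1 <- resolve_tags(config$tags_y1)
    tags2 <- resolve_tags(config$tags_y2)
    catch <- if (is.null(config$catch)) NULL
             else if (is.data.frame(config$catch)) config$catch
             else read.csv(config$catch, stringsAsFactors = FALSE)
    captive <- if (is.null(config$captive)) NULL
               else if (is.data.frame(config$captive)) config$captive
               else read_captive_series(config$captive)
  }
  report$tags <- list(year1 = tags1, year2 = tags2)

  # increments + filter audit
  flt1 <- if (nrow(tags1)) filter_increments(increment_records(tags1)) else {
    warn("no year-1 tag records")
    filter_increments(increment_records(tags1[0, , drop = FALSE]))
  }
  flt2 <- if (!is.null(tags2) && nrow(tags2)) {
    filter_increments(increment_records(tags2))
  }
  report$filter <- list(year1 = flt1, year2 = flt2)

  kept1 <- flt1$kept
  report$table <- if (nrow(kept1)) {
    build_size_class_table(kept1, config$class_edges, config$conversions)
  }

  report$histograms <- lapply(split(kept1$dl, kept1$sex),
                              increment_histogram)

  male <- kept1[kept1$sex == "M", , drop = FALSE]
  if (nrow(male)) {
    cls <- classify_moult_modes(male$dl, config$boundaries)
    report$modes <- cls
    one <- male$l1[cls$labels == "1 moult"]
    two <- male$l1[cls$labels == "2 moults"]
    report$mode_size_test <- if (length(one) >= 2 && length(two) >= 2) {
      compare_mode_starting_sizes(one, two)
    } else {
      warn("too few classified males for the starting-size comparison")
      NULL
    }
  }

  # Powell-Wetherall per sex, then forced Gulland-Holt at the estimate
  report$powell_wetherall <- list()
  report$gulland_holt <- list()
  for (s in c("M", "F")) {
    if (is.null(catch)) next
    cl_s <- catch$cl_mm[catch$sex == s]
    if (length(cl_s) < config$min_tail_count * 3) next
    pw <- tryCatch(
      powell_wetherall(cl_s, config$recruit_length, config$bin_width,
                       config$min_tail_count),
      error = function(e) {
        warn(sprintf("Powell-Wetherall failed for sex %s: %s", s,
                     conditionMessage(e)))
        NULL
      })
    report$powell_wetherall[[s]] <- pw
    if (is.null(pw)) next
    rec1 <- kept1[kept1$sex == s, , drop = FALSE]
    rec2 <- if (!is.null(flt2)) {
      flt2$kept[flt2$kept$sex == s, , drop = FALSE]
    }
    if (nrow(rec1)) {
      report$gulland_holt[[s]] <- pool_and_estimate(rec1, rec2, pw$l_inf_hat)
    }
  }

  if (!is.null(captive) && nrow(captive)) {
    report$captive_moults <- do.call(rbind, lapply(
      split(captive, captive$tag_id), function(d) {
        ev <- detect_captive_moults(d$cl_mm, d$obs_date, d$moult_flag)
        if (nrow(ev)) cbind(tag_id = d$tag_id[1], sex = d$sex[1], ev)
      }))
  }

  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config)
  class(report) <- "growth_report"
  report
}

write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(report$table)) {
    write.csv(as.data.frame(report$table), p("size_class_table.csv"),
              row.names = FALSE)
  }
  kv <- character(0)
  add <- function(key, val) kv <<- c(kv, sprintf("%s=%s", key,
                                                 format(val, digits = 10)))
  for (s in names(report$powell_wetherall)) {
    pw <- report$powell_wetherall[[s]]
    if (is.null(pw)) next
    add(paste0("pw_a_", s), pw$a); add(paste0("pw_b_", s), pw$b)
    add(paste0("l_inf_", s), pw$l_inf_hat)
    add(paste0("z_over_k_", s), pw$z_over_k_hat)
  }
  for (s in names(report$gulland_holt)) {
    gh <- report$gulland_holt[[s]]
    if (is.null(gh)) next
    add(paste0("k_pooled_", s), gh$pooled$k_hat)
    add(paste0("k_n_", s), gh$pooled$n_records)
  }
  if (!is.null(report$filter$year1)) {
    for (r in names(report$filter$year1$audit)) {
      add(paste0("dropped_y1_", gsub("[^a-z]+", "_", r)),
          report$filter$year1$audit[[r]])
    }
  }
  writeLines(kv, p("fit_report.txt"))
  if (length(report$warnings)) writeLines(report$warnings, p("warnings.txt"))
  invisible(config$out_dir)
}

#' @export
print.growth_report <- function(x, ...) {
  cat("Growth estimation report\n")
  n1 <- if (!is.null(x$tags$year1)) nrow(x$tags$year1) else 0
  cat(sprintf("  year-1 tags: %d (%d kept after filtering)\n",
              n1, nrow(x$filter$year1$kept)))
  for (s in names(x$powell_wetherall)) {
    pw <- x$powell_wetherall[[s]]
    if (!is.null(pw)) {
      cat(sprintf("  %s: L_inf = %.2f mm", s, pw$l_inf_hat))
      gh <- x$gulland_holt[[s]]
      if (!is.null(gh)) cat(sprintf(", pooled k = %.4f /yr", gh$pooled$k_hat))
      cat("\n")
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
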