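#' Draw a seasonal moult schedule
#'
#' Moult times (days since release) for one individual over a period at
#' liberty. Each 365.25-day window at liberty contains one moult for
#' females; males receive one moult plus a second with probability
#' `p(CL) = intercept + slope * CL` (clamped to \[0, 1\]), and optionally a
#' rare third with probability `p_third_moult`. Moult months are drawn from
#' the sex-specific monthly weights and placed uniformly within the month on
#' the calendar anchored at `release_date`; a moult scheduled after the
#' recapture day simply never shows up in the realised growth (the animal is
#' recaptured before moulting -- the source of zero-growth records).
#'
#' Uses the current RNG stream; seed control belongs to the callers
#' ([simulate_tag_recapture()] and friends).
#'
#' Double-moulting males moult roughly in antiphase: the second (and any
#' third) moult falls 4--6 months after the previous one, a biannual moult
#' cycle, so single and double moulters end their growth year in opposite
#' seasons -- the structure that makes the male increment distribution
#' bimodal.
#'
#' @param sex `"M"` or `"F"`.
#' @param cl Carapace length at release, mm (drives the male second-moult
#'   probability).
#' @param config A [sim_config()].
#' @param liberty_days Length of the period at liberty, days; determines how
#'   many annual windows are scheduled.
#' @return Sorted numeric vector of moult times, days since release.
#' @export
draw_moult_schedule <- function(sex, cl, config, liberty_days = 365) {
  stopifnot(inherits(config, "sim_config"), sex %in% c("M", "F"))
  w <- if (sex == "M") config$moult_weights_m else config$moult_weights_f
  n_windows <- max(1L, ceiling(liberty_days / 365.25))
  times <- numeric(0)
  for (j in seq_len(n_windows)) {
    n_moults <- 1L
    if (sex == "M") {
      p2 <- clamp01(config$p_second_moult[["intercept"]] +
                      config$p_second_moult[["slope"]] * cl)
      n_moults <- n_moults + rbinom(1L, 1L, p2)
      if (config$p_third_moult > 0) {
        n_moults <- n_moults + rbinom(1L, 1L, config$p_third_moult)
      }
    }
    month <- sample.int(12L, 1L, prob = w)
    win_start <- (j - 1) * 365.25
    t1 <- moult_day_in_window(month, win_start, config$release_date)
    win_times <- t1
    while (length(win_times) < n_moults) {
      # subsequent moults roughly in antiphase, 4-6 months later
      win_times <- c(win_times,
                     win_times[length(win_times)] + runif(1, 120, 180))
    }
    times <- c(times, win_times)
  }
  sort(times)
}

# Place a moult in calendar `month` so that its offset from `release_date`
# falls inside [window_start, window_start + 365.25); day-of-month uniform.
# Months straddling the window edge are folded back into the window.
moult_day_in_window <- function(month, window_start, release_date) {
  yr0 <- as.integer(format(release_date, "%Y")) + floor(window_start / 365.25)
  u <- runif(1)
  best <- NA_real_
  for (yr in yr0 + (-1:2)) {
    first <- as.Date(sprintf("%04d-%02d-01", yr, month))
    nxt <- if (month == 12L) {
      as.Date(sprintf("%04d-01-01", yr + 1L))
    } else {
      as.Date(sprintf("%04d-%02d-01", yr, month + 1L))
    }
    nd <- as.numeric(nxt - first)
    off <- as.numeric(first - release_date) + u * nd
    if (off >= window_start && off < window_start + 365.25) return(off)
    if (is.na(best)) best <- off
  }
  window_start + ((best - window_start) %% 365.25)
}

#' Sample a steady-state catch length distribution
#'
#' Lengths from the equilibrium population implied by VBGF growth, constant
#' recruitment and constant exponential total mortality Z: density
#' proportional to \eqn{(L_\infty - L)^{Z/k - 1}} on `[l_c, l_inf]`, sampled
#' by inverse CDF, \eqn{L = L_\infty - (L_\infty - L_c)(1-u)^{k/Z}}. The
#' mean length above any cutoff of such a population follows the
#' Beverton--Holt relation, so a Powell--Wetherall regression on it recovers
#' `l_inf`.
#'
#' @param n Number of lengths to draw.
#' @param l_inf Asymptotic length, mm.
#' @param z_over_k Mortality/growth ratio, `> 0`.
#' @param l_c Smallest retained length, mm (`< l_inf`).
#' @return Numeric vector of `n` lengths in `[l_c, l_inf]`.
#' @export
sample_steady_state_lengths <- function(n, l_inf, z_over_k, l_c) {
  stopifnot(n >= 1)
  if (!is_scalar_number(z_over_k) || z_over_k <= 0) {
    stop("`z_over_k` must be > 0", call. = FALSE)
  }
  if (l_c >= l_inf) stop("`l_c` must be below `l_inf`", call. = FALSE)
  u <- runif(n)
  l_inf - (l_inf - l_c) * (1 - u)^(1 / z_over_k)
}

#' Closed-form CDF of the steady-state length distribution
#'
#' @inheritParams sample_steady_state_lengths
#' @param q Lengths at which to evaluate the CDF.
#' @return `P(L <= q)`.
#' @export
steady_state_cdf <- function(q, l_inf, z_over_k, l_c) {
  p <- 1 - ((l_inf - pmin(pmax(q, l_c), l_inf)) / (l_inf - l_c))^z_over_k
  p[q < l_c] <- 0
  p[q >= l_inf] <- 1
  p
}

#' Simulate a tag-recapture experiment
#'
#' Individual-based simulation of the tagging design: release lengths
#' uniform on the sex-specific ranges (rounded to 0.1 mm), liberty durations
#' Normal truncated positive, seasonal stepped growth via
#' [draw_moult_schedule()] and [stepped_growth()], and recapture lengths
#' measured with additive Gaussian error then rounded to 0.1 mm. With
#' `measurement_sd = 0` recapture length can never fall below release
#' length; individuals recaptured before their first moult yield
#' zero-growth records, the class that [filter_increments()] drops.
#'
#' @param config A [sim_config()].
#' @param n Number of tagged individuals.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A data frame of tag records: `tag_id`, `sex`, `release_date`,
#'   `release_cl_mm`, `recapture_date`, `recapture_cl_mm`.
#' @export
simulate_tag_recapture <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  sex <- ifelse(runif(n) < config$prop_male, "M", "F")
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sex[i]
    rr <- if (s == "M") config$release_range_m else config$release_range_f
    li <- if (s == "M") config$l_inf_m else config$l_inf_f
    k <- if (s == "M") config$k_m else config$k_f
    cl0 <- round(runif(1, rr[1], rr[2]), 1)
    liberty <- rnorm(1, config$liberty_days_mean, config$liberty_days_sd)
    while (liberty <= 1) {
      liberty <- rnorm(1, config$liberty_days_mean, config$liberty_days_sd)
    }
    recap_day <- round(liberty)
    sched <- draw_moult_schedule(s, cl0, config, liberty_days = liberty)
    traj <- stepped_growth(cl0, sched, li, k, recapture_day = recap_day,
                           sex = s)
    cl1 <- round(traj$final_cl + rnorm(1, 0, config$measurement_sd), 1)
    rec[[i]] <- data.frame(
      tag_id = sprintf("CWT%05d", i), sex = s,
      release_date = config$release_date, release_cl_mm = cl0,
      recapture_date = config$release_date + recap_day,
      recapture_cl_mm = cl1, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Simulate a catch length-frequency sample
#'
#' Per-sex steady-state lengths (see [sample_steady_state_lengths()]) with
#' lengths rounded to 0.1 mm and a sampling month drawn uniformly from the
#' fishing season (April--September).
#'
#' @param config A [sim_config()].
#' @param n Total number of measured individuals.
#' @param seed Integer seed (defaults to `config$seed + 1` so tag and catch
#'   samples drawn from one configuration are independent).
#' @return Data frame with `sex`, `month`, `cl_mm`.
#' @export
simulate_catch_sample <- function(config, n, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  sex <- ifelse(runif(n) < config$prop_male, "M", "F")
  n_m <- sum(sex == "M")
  cl <- numeric(n)
  if (n_m > 0) {
    cl[sex == "M"] <- sample_steady_state_lengths(
      n_m, config$l_inf_m, config$z_over_k_m, config$l_c)
  }
  if (n_m < n) {
    cl[sex == "F"] <- sample_steady_state_lengths(
      n - n_m, config$l_inf_f, config$z_over_k_f, config$l_c)
  }
  data.frame(sex = sex, month = sample(4:9, n, replace = TRUE),
             cl_mm = round(cl, 1), stringsAsFactors = FALSE)
}

#' Simulate captive monthly monitoring series
#'
#' Monthly carapace-length observations over one year of captivity.
#' A configurable fraction of individuals moults exactly once, in a month
#' drawn from the sex-specific seasonal weights, gaining a uniform 1--2 mm
#' (captive increments are much smaller than wild ones); the rest do not
#' moult. Two observation months are skipped, mimicking gaps in monitoring,
#' and half of the moults also carry an external evidence flag (shell
#' fragments or a soft shell).
#'
#' @param config A [sim_config()].
#' @param n_m,n_f Numbers of captive males and females.
#' @param p_moult_m,p_moult_f Per-sex probability of moulting within the
#'   year (defaults 47/111 and 63/121).
#' @param start First observation month (`Date` or string).
#' @param skip_months Integer indices (1--12 within the series) of skipped
#'   observation months.
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return Data frame with `tag_id`, `sex`, `obs_date`, `cl_mm`,
#'   `moult_flag`.
#' @export
simulate_captive_series <- function(config, n_m = 111, n_f = 121,
                                    p_moult_m = 47 / 111, p_moult_f = 63 / 121,
                                    start = "2014-04-01",
                                    skip_months = c(7L, 12L),
                                    seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  start <- as.Date(start)
  obs_dates <- seq(start, by = "month", length.out = 12L)
  obs_idx <- setdiff(seq_len(12L), skip_months)
  sexes <- c(rep("M", n_m), rep("F", n_f))
  out <- vector("list", length(sexes))
  for (i in seq_along(sexes)) {
    s <- sexes[i]
    rr <- if (s == "M") c(26.2, 53.0) else c(23.5, 41.2)
    w <- if (s == "M") config$moult_weights_m else config$moult_weights_f
    p <- if (s == "M") p_moult_m else p_moult_f
    cl0 <- round(runif(1, rr[1], rr[2]), 1)
    cl <- rep(cl0, 12L)
    flag <- rep(FALSE, 12L)
    if (runif(1) < p) {
      cal_months <- as.integer(format(obs_dates, "%m"))
      moult_at <- sample.int(12L, 1L, prob = w[cal_months])
      if (moult_at < 12L) {
        gain <- round(runif(1, 1, 2), 1)
        cl[(moult_at + 1L):12L] <- cl0 + gain
        flag[moult_at + 1L] <- runif(1) < 0.5
      }
    }
    out[[i]] <- data.frame(
      tag_id = sprintf("CAP%04d", i), sex = s,
      obs_date = obs_dates[obs_idx], cl_mm = cl[obs_idx],
      moult_flag = flag[obs_idx], stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
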