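# Build an increment-record data frame directly from the derived quantities
# a Gulland-Holt fit consumes (l1/l2 chosen so lbar and rate come out exact).
mk_gh_records <- function(lbar, rate, dt = 365.25, sex = "M") {
  dl <- rate * dt / 365.25
  data.frame(tag_id = sprintf("T%03d", seq_along(lbar)), sex = sex,
             l1 = lbar - dl / 2, l2 = lbar + dl / 2, dt = dt, dl = dl,
             lbar = lbar, rate = rate, stringsAsFactors = FALSE)
}

# Tag-record data frame with explicit release/recapture fields.
mk_tags <- function(l1, l2, dt = 365, sex = "M", tag_id = NULL) {
  n <- length(l1)
  data.frame(tag_id = tag_id %||% sprintf("CWT%04d", seq_len(n)),
             sex = rep_len(sex, n),
             release_date = rep(as.Date("2013-06-19"), n),
             release_cl_mm = l1,
             recapture_date = as.Date("2013-06-19") + rep_len(dt, n),
             recapture_cl_mm = l2, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent rejection sampler on the steady-state density
# f(L) ~ (l_inf - L)^(z_over_k - 1) on [l_c, l_inf]; used as an oracle
# against the package's inverse-CDF sampler.
rejection_steady_state <- function(n, l_inf, z_over_k, l_c) {
  out <- numeric(0)
  fmax <- if (z_over_k >= 1) (l_inf - l_c)^(z_over_k - 1) else stop("need z/k >= 1")
  while (length(out) < n) {
    cand <- runif(2 * n, l_c, l_inf)
    acc <- runif(2 * n) < ((l_inf - cand)^(z_over_k - 1)) / fmax
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

# Two-sample Kolmogorov-Smirnov distance without p-value machinery.
ks_distance <- function(x, cdf, ...) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf(x, ...)
  max(abs(seq_len(n) / n - fx), abs((seq_len(n) - 1) / n - fx))
}

# Brute-force 1-D least squares for the forced (through-origin) regression:
# coarse grid scan, then an exact parabolic vertex step (the RSS is a
# quadratic in k, so three points pin the minimum to machine precision).
brute_forced_k <- function(rate, x, lo = -5, hi = 5) {
  rss <- function(k) sum((rate - k * x)^2)
  grid <- seq(lo, hi, length.out = 2001)
  k0 <- grid[which.min(vapply(grid, rss, numeric(1)))]
  h <- (hi - lo) / 2000
  fm <- rss(k0 - h); f0 <- rss(k0); fp <- rss(k0 + h)
  k0 + h * (fm - fp) / (2 * (fm - 2 * f0 + fp))
}
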