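test_that("filtering reproduces the study's accounting of a tagging year", {
  # 207 recaptures: 100 males (one unreadable among them) and 107 females
  # (7 with zero or negative growth) -> 99 + 100 kept
  tags <- rbind(
    mk_tags(l1 = rep(32, 100), l2 = rep(35, 100), sex = "M"),
    mk_tags(l1 = rep(33, 107), l2 = c(rep(33, 5), 32.5, 32.9, rep(34.4, 100)),
            sex = "F")
  )
  tags$tag_id <- sprintf("CWT%04d", seq_len(207))
  tags$tag_id[100] <- NA
  flt <- filter_increments(increment_records(tags))
  expect_identical(nrow(flt$kept), 199L)
  expect_identical(unname(flt$audit["non-positive growth"]), 7L)
  expect_identical(unname(flt$audit["unreadable tag"]), 1L)
  expect_equal(as.vector(table(flt$kept$sex)), c(100, 99))  # F, M
})

test_that("filtering keeps everything when all growth is positive", {
  tags <- mk_tags(l1 = c(30, 31), l2 = c(32, 33))
  flt <- filter_increments(increment_records(tags))
  expect_identical(nrow(flt$kept), 2L)
  expect_identical(nrow(flt$dropped), 0L)
})

test_that("a record with equal lengths is dropped as non-positive growth", {
  flt <- filter_increments(increment_records(mk_tags(30, 30)))
  expect_identical(flt$dropped$reason, "non-positive growth")
})

test_that("mean length above a cutoff handles point masses and symmetry", {
  expect_equal(mean_length_above_cutoff(rep(50, 7), 40), 50)
  # uniform mass on [38, 70.8] is symmetric about its midpoint
  u <- seq(38.0005, 70.7995, length.out = 4001)
  expect_equal(mean_length_above_cutoff(u, 38), (38 + 70.8) / 2,
               tolerance = 1e-6)
  expect_error(mean_length_above_cutoff(c(30, 35), 40), "cutoff")
})

test_that("steady-state tail means follow the Beverton-Holt relation", {
  set.seed(19)
  x <- sample_steady_state_lengths(2e5, 70.8, 2, 25)
  # closed form: (Z L' + k L_inf)/(Z + k) with Z/k = 2
  expect_equal(mean_length_above_cutoff(x, 38), (2 * 38 + 70.8) / 3,
               tolerance = 0.005)
})

test_that("Powell-Wetherall recovers l_inf exactly from exact points", {
  lp <- seq(38, 62, by = 2)
  lbar <- (2 * lp + 70.8) / 3
  fit <- powell_wetherall_points(lp, lbar)
  expect_equal(fit$a, 23.6, tolerance = 1e-9)
  expect_equal(fit$b, -1 / 3, tolerance = 1e-12)
  expect_equal(fit$l_inf_hat, 70.8, tolerance = 1e-9)
  expect_equal(fit$z_over_k_hat, 2, tolerance = 1e-9)
})

test_that("Powell-Wetherall refuses degenerate inputs", {
  expect_error(powell_wetherall_points(c(38, 38), c(50, 50)), "degenerate")
  # increasing y over L' implies b >= 0
  expect_error(powell_wetherall_points(c(38, 40, 42), c(50, 53, 56)),
               "degenerate")
  # slope at or below -1 (tail mean equal to the cutoff everywhere)
  expect_error(powell_wetherall_points(c(38, 40, 42), c(39, 39, 39)),
               "degenerate")
})

test_that("Powell-Wetherall is invariant to rescaling all counts", {
  lf1 <- length_frequency(seq(38, 58, 2), c(40, 34, 26, 20, 16, 12, 9, 6, 5, 5, 5))
  lf3 <- length_frequency(seq(38, 58, 2), 3 * c(40, 34, 26, 20, 16, 12, 9, 6, 5, 5, 5))
  f1 <- powell_wetherall(lf1, 38)
  f3 <- powell_wetherall(lf3, 38)
  expect_equal(f1$l_inf_hat, f3$l_inf_hat)
  expect_equal(f1$b, f3$b)
})

test_that("Powell-Wetherall on a large steady-state sample recovers l_inf", {
  set.seed(23)
  x <- sample_steady_state_lengths(1e5, 55.2, 2, 38)
  fit <- powell_wetherall(x, recruit_length = 38)
  expect_equal(fit$l_inf_hat, 55.2, tolerance = 1 / 55.2)
  expect_lt(fit$b, 0)
  expect_gt(fit$b, -1)
})

test_that("forced Gulland-Holt solves the one-point case by hand", {
  rec <- mk_gh_records(lbar = 50, rate = 2)
  fit <- forced_gulland_holt(rec, l_inf = 70)
  expect_equal(fit$k_hat, 0.1)
  expect_identical(fit$n_records, 1L)
})

test_that("forced Gulland-Holt recovers k exactly from noise-free rates", {
  lbar <- seq(28, 60, by = 0.5)
  rec <- mk_gh_records(lbar, rate = 0.161 * (70.8 - lbar))
  fit <- forced_gulland_holt(rec, l_inf = 70.8)
  expect_equal(fit$k_hat, 0.161, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)
})

test_that("the forced estimator is linear in the response", {
  set.seed(29)
  lbar <- runif(40, 28, 60)
  rate <- 0.15 * (70.8 - lbar) + rnorm(40, 0, 0.5)
  k1 <- forced_gulland_holt(mk_gh_records(lbar, rate), 70.8)$k_hat
  k2 <- forced_gulland_holt(mk_gh_records(lbar, rate / 2), 70.8)$k_hat
  expect_equal(k2, k1 / 2, tolerance = 1e-9)
})

test_that("forced Gulland-Holt matches a brute-force 1-D least-squares search", {
  set.seed(37)
  for (i in 1:5) {
    lbar <- runif(60, 25, 65)
    rate <- runif(60, -1, 8)  # arbitrary data, not necessarily VBGF-like
    rec <- mk_gh_records(lbar, rate)
    fit <- forced_gulland_holt(rec, l_inf = 70.8)
    brute <- brute_forced_k(rec$rate, 70.8 - rec$lbar)
    expect_equal(fit$k_hat, brute, tolerance = 1e-9)
  }
})

test_that("records at or beyond l_inf are excluded with a warning", {
  rec <- mk_gh_records(c(50, 72), c(2, 1))
  expect_warning(fit <- forced_gulland_holt(rec, 70), "excluded")
  expect_identical(fit$n_records, 1L)
  expect_error(suppressWarnings(forced_gulland_holt(mk_gh_records(72, 1), 70)),
               "no usable")
})

test_that("pooling years behaves like the weighted forced fit it is", {
  set.seed(43)
  lbar1 <- runif(50, 28, 60)
  y1 <- mk_gh_records(lbar1, 0.16 * (70.8 - lbar1) + rnorm(50, 0, 0.4))
  lbar2 <- runif(30, 28, 60)
  y2 <- mk_gh_records(lbar2, 0.19 * (70.8 - lbar2) + rnorm(30, 0, 0.4))
  # year1 alone
  p1 <- pool_and_estimate(y1, NULL, 70.8)
  expect_equal(p1$pooled$k_hat, forced_gulland_holt(y1, 70.8)$k_hat)
  expect_null(p1$year2)
  # pooling a set with itself changes nothing
  pii <- pool_and_estimate(y1, y1, 70.8)
  expect_equal(pii$pooled$k_hat, p1$pooled$k_hat)
  # pooled estimate lies between the two per-year estimates
  p12 <- pool_and_estimate(y1, y2, 70.8)
  ks <- sort(c(p12$year1$k_hat, p12$year2$k_hat))
  expect_gte(p12$pooled$k_hat, ks[1])
  expect_lte(p12$pooled$k_hat, ks[2])
})
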