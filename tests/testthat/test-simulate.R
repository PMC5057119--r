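test_that("females always get exactly one moult per year at liberty", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  for (i in 1:50) {
    expect_length(draw_moult_schedule("F", 33, cfg, liberty_days = 344), 1L)
    expect_length(draw_moult_schedule("F", 33, cfg, liberty_days = 700), 2L)
  }
})

test_that("male second-moult frequency follows the configured probability", {
  cfg <- sim_config(p_second_moult = c(intercept = 0.5, slope = 0), seed = 5)
  set.seed(5)
  n2 <- sum(vapply(seq_len(10000), function(i) {
    length(draw_moult_schedule("M", 33, cfg, liberty_days = 344))
  }, numeric(1)) == 2L)
  expect_equal(n2 / 10000, 0.5, tolerance = 0.04)
})

test_that("size-dependent double moulting makes single moulters larger on average", {
  cfg <- sim_config(seed = 9)
  set.seed(9)
  cl <- runif(800, 26.9, 40.2)
  n_moults <- vapply(cl, function(x) {
    length(draw_moult_schedule("M", x, cfg, liberty_days = 344))
  }, numeric(1))
  expect_gt(mean(cl[n_moults == 1]), mean(cl[n_moults == 2]))
})

test_that("moult times respect the seasonal calendar", {
  # May-only weights from a 19-June release put the year-1 moult 316-347
  # days out (May of the following year)
  cfg <- recovery_sim_config(seed = 2)
  set.seed(2)
  t1 <- replicate(200, draw_moult_schedule("F", 33, cfg, liberty_days = 344))
  expect_true(all(t1 >= 316 & t1 < 347))
})

test_that("steady-state sampler has the stated support and moments", {
  set.seed(11)
  x <- sample_steady_state_lengths(20000, 70.8, z_over_k = 1, l_c = 38)
  expect_true(all(x >= 38 & x <= 70.8))
  # z/k = 1 is uniform
  expect_equal(mean(x), (38 + 70.8) / 2, tolerance = 0.05)
  expect_lt(ks_distance(x, function(q) punif(q, 38, 70.8)), 0.02)
  # analytic mean for z/k = 2: l_inf - (2/3) (l_inf - l_c)
  y <- sample_steady_state_lengths(20000, 70.8, z_over_k = 2, l_c = 38)
  expect_equal(mean(y), 70.8 - (70.8 - 38) * 2 / 3, tolerance = 0.05)
  expect_error(sample_steady_state_lengths(10, 70.8, -1, 38), "z_over_k")
  expect_error(sample_steady_state_lengths(10, 70.8, 2, 75), "l_c")
})

test_that("inverse-CDF sampler matches the closed-form CDF and a rejection oracle", {
  set.seed(13)
  x <- sample_steady_state_lengths(1e4, 70.8, 2, 38)
  expect_lt(ks_distance(x, steady_state_cdf, l_inf = 70.8, z_over_k = 2,
                        l_c = 38), 0.02)
  y <- rejection_steady_state(1e4, 70.8, 2, 38)
  d2 <- suppressWarnings(stats::ks.test(x, y)$statistic)
  expect_lt(unname(d2), 0.025)
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- sim_config(seed = 21)
  expect_identical(simulate_tag_recapture(cfg, 200),
                   simulate_tag_recapture(cfg, 200))
  expect_identical(simulate_catch_sample(cfg, 500),
                   simulate_catch_sample(cfg, 500))
  expect_identical(simulate_captive_series(cfg, n_m = 20, n_f = 20),
                   simulate_captive_series(cfg, n_m = 20, n_f = 20))
})

test_that("without measurement error no increment is negative", {
  cfg <- sim_config(measurement_sd = 0, seed = 17)
  tags <- simulate_tag_recapture(cfg, 400)
  inc <- increment_records(tags)
  expect_true(all(inc$dl >= 0))
})

test_that("male increments are bimodal, female increments unimodal", {
  cfg <- sim_config(seed = 31)
  tags <- simulate_tag_recapture(cfg, 2500)
  kept <- filter_increments(increment_records(tags))$kept
  hm <- increment_histogram(kept$dl[kept$sex == "M"], bin_width = 1)
  hf <- increment_histogram(kept$dl[kept$sex == "F"], bin_width = 1)
  expect_gte(count_modes(hm$count), 2L)
  expect_identical(count_modes(hf$count), 1L)
})

test_that("captive series carry at most one moult and the configured rates", {
  cfg <- sim_config(seed = 41)
  cap <- simulate_captive_series(cfg, n_m = 150, n_f = 150,
                                 p_moult_m = 0.4, p_moult_f = 0.6)
  per <- split(cap, cap$tag_id)
  n_events <- vapply(per, function(d) {
    nrow(detect_captive_moults(d$cl_mm, d$obs_date, d$moult_flag))
  }, numeric(1))
  expect_true(all(n_events <= 1))
  sex1 <- vapply(per, function(d) d$sex[1], character(1))
  # detected rates can undershoot the moulting rates (late moults fall in
  # the unobserved tail) but must stay in a sane band
  expect_gt(mean(n_events[sex1 == "M"] > 0), 0.2)
  expect_gt(mean(n_events[sex1 == "F"] > 0), 0.4)
})

test_that("sim config validation enforces the documented invariants", {
  expect_error(sim_config(k_m = 3.5), "in \\(0, 3\\)")
  expect_error(sim_config(l_c = 80), "l_c")
  expect_error(sim_config(z_over_k_f = 0), "Z/k")
  expect_error(sim_config(release_range_m = c(40, 75)), "below l_inf")
  expect_error(sim_config(moult_weights_f = rep(0, 12)), "weights")
})
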