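test_that("size-class table conserves totals and matches hand arithmetic", {
  set.seed(53)
  l1 <- runif(80, 26, 40)
  dl <- runif(80, 0.2, 8)
  rec <- mk_tags(l1, l1 + dl, sex = sample(c("M", "F"), 80, TRUE))
  tab <- build_size_class_table(increment_records(rec))
  ov <- attr(tab, "overall")
  # sum of n * class mean equals the total increment, per sex
  for (s in c("M", "F")) {
    rows <- tab[tab$sex == s & tab$n > 0, ]
    expect_equal(sum(rows$n * rows$mean_dcl),
                 sum(dl[rec$sex == s]), tolerance = 1e-10)
    expect_identical(sum(rows$n), ov$n[ov$sex == s])
    # weighted class means reproduce the overall mean
    expect_equal(overall_mean_from_classes(rows$n, rows$mean_dcl),
                 ov$mean_dcl[ov$sex == s])
  }
})

test_that("a single record yields one occupied class with zero SE", {
  rec <- increment_records(mk_tags(31, 34.2))
  tab <- build_size_class_table(rec)
  occ <- tab[tab$n > 0, ]
  expect_identical(nrow(occ), 1L)
  expect_equal(occ$mean_dcl, 3.2)
  expect_identical(occ$se_dcl, 0)
})

test_that("records outside the class range are excluded with a message", {
  rec <- increment_records(mk_tags(c(31, 55), c(33, 57)))
  expect_message(tab <- build_size_class_table(rec), "outside")
  expect_identical(sum(tab$n), 1L)
})

test_that("increment histograms conserve counts", {
  set.seed(59)
  dl <- runif(200, 0, 12)
  h <- increment_histogram(dl, bin_width = 1)
  expect_identical(sum(h$count), 200L)
  expect_true(all(h$bin_lower == floor(h$bin_lower)))
  h0 <- increment_histogram(numeric(0))
  expect_identical(sum(h0$count), 0L)
})

test_that("moult-mode classification partitions increments as documented", {
  cls <- classify_moult_modes(c(3.0, 6.0, 5.0, 4.49, 5.50, 8.49, 8.5, -0.5))
  expect_equal(as.character(cls$labels),
               c("1 moult", "2 moults", "unclassified", "unclassified",
                 "2 moults", "2 moults", ">=3 moults", "unclassified"))
  expect_identical(sum(cls$counts), 8L)
  expect_error(moult_mode_boundaries(mode1_max = 6, mode2_range = c(5, 8)),
               "mode2_range")
})

test_that("starting-size t test agrees with sums-based brute force", {
  g1 <- c(30, 31, 32); g2 <- c(33, 34, 35)
  res <- compare_mode_starting_sizes(g1, g2)
  # pooled-variance t computed from group sums
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 4
  t_brute <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_brute)
  expect_equal(abs(res$t), 3.674, tolerance = 1e-3)
  expect_identical(res$df, 4)
  # identical groups give t = 0
  expect_equal(compare_mode_starting_sizes(g1, g1)$t, 0)
  # Welch option changes the df convention
  expect_lt(compare_mode_starting_sizes(g1, c(33, 35, 40),
                                        var_equal = FALSE)$df, 4)
})

test_that("Mann-Whitney U follows the min-U convention", {
  res <- wild_vs_captive_test(c(3, 4, 5), c(1, 1, 2))
  expect_identical(unname(res$U), 0)          # complete separation
  same <- wild_vs_captive_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(res$median_wild, 4)
  expect_equal(res$range_captive, c(1, 2))
  first <- wild_vs_captive_test(c(3, 4, 5), c(1, 1, 2), convention = "first")
  expect_identical(unname(first$U), 9)
})

test_that("wild males outgrow captive males in simulated data", {
  cfg <- sim_config(seed = 61)
  tags <- simulate_tag_recapture(cfg, 600)
  kept <- filter_increments(increment_records(tags))$kept
  cap <- simulate_captive_series(cfg, n_m = 120, n_f = 0)
  cap_dl <- unlist(lapply(split(cap, cap$tag_id), function(d) {
    detect_captive_moults(d$cl_mm, d$obs_date, d$moult_flag)$dcl
  }))
  res <- wild_vs_captive_test(kept$dl[kept$sex == "M"], cap_dl)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$median_wild, res$median_captive)
})

test_that("Spearman correlation handles monotone and hand-ranked cases", {
  expect_equal(size_growth_correlation(1:5, 10 - (1:5))$rho, -1)
  expect_equal(size_growth_correlation(1:5, 2 * (1:5))$rho, 1)
  res <- size_growth_correlation(c(30, 32, 34, 36), c(5, 4, 6, 3))
  expect_equal(res$rho, -0.4)
})

test_that("larger simulated males grow less (negative rank correlation)", {
  cfg <- sim_config(seed = 67)
  tags <- simulate_tag_recapture(cfg, 800)
  kept <- filter_increments(increment_records(tags))$kept
  m <- kept[kept$sex == "M", ]
  res <- size_growth_correlation(m$l1, m$dl)
  expect_lt(res$rho, 0)
})

test_that("captive moult detection applies the sustained 0.5 mm rule", {
  ev <- detect_captive_moults(c(30.0, 30.0, 31.2, 31.2))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$step, 2L)
  expect_equal(ev$dcl, 1.2)
  # a 0.4 mm rise is below threshold
  expect_identical(nrow(detect_captive_moults(c(30.0, 30.4, 30.4))), 0L)
  # a rise that is not sustained does not count
  expect_identical(nrow(detect_captive_moults(c(30.0, 30.8, 30.0))), 0L)
  # an external flag counts even without a size jump
  ev2 <- detect_captive_moults(c(30.0, 30.2, 30.2),
                               flags = c(FALSE, TRUE, FALSE))
  expect_identical(ev2$source, "flag")
  expect_warning(detect_captive_moults(30), "fewer than 2")
})

test_that("moult detection never fires on a non-increasing series", {
  set.seed(73)
  for (i in 1:20) {
    cl <- 40 - cumsum(abs(rnorm(8, 0, 0.6)))
    expect_identical(nrow(detect_captive_moults(cl)), 0L)
  }
})
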