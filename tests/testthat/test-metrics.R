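# Stability ratio, replicate statistics, group comparison, stoichiometry
# ratios, calibration and detection limits.

test_that("stability ratio matches direct substitution", {
  tgt <- ann_row(100, sn = 50)
  frags <- rbind(ann_row(10, sn = 20, label = "fragment"),
                 ann_row(5, sn = 15, label = "fragment"))
  res <- stability_ratio(tgt, frags)
  expect_equal(res$sr, 0.85)
  expect_equal(res$n_fragments_used, 2L)
  expect_equal(res$fragment_sum, 15)
  expect_false(res$negative)

  # no fragments above the threshold: empty sum, SR = 1
  expect_equal(stability_ratio(tgt, NULL)$sr, 1.0)
  low <- rbind(ann_row(10, sn = 9.99, label = "fragment"))
  expect_equal(stability_ratio(tgt, low)$sr, 1.0)
  expect_equal(stability_ratio(tgt, low)$n_fragments_used, 0L)

  # fragments exceeding the target: negative SR, flagged not clamped
  heavy <- rbind(ann_row(70, sn = 30, label = "fragment"),
                 ann_row(50, sn = 25, label = "fragment"))
  res2 <- stability_ratio(tgt, heavy)
  expect_equal(res2$sr, -0.2)
  expect_true(res2$negative)
})

test_that("sub-threshold fragments are excluded, sub-threshold target raises", {
  tgt <- ann_row(100, sn = 50)
  frags <- rbind(ann_row(10, sn = 30, label = "fragment"),
                 ann_row(40, sn = 5, label = "fragment"))
  expect_equal(stability_ratio(tgt, frags)$sr, 0.9)

  weak <- ann_row(100, sn = 9.5)
  expect_error(stability_ratio(weak, frags),
               "target below quantification limit")
  # threshold is configurable
  expect_equal(stability_ratio(weak, frags, sn_threshold = 5)$sr, 0.5)
})

test_that("SR is invariant to uniform intensity scaling", {
  set.seed(61)
  for (i in 1:10) {
    tgt_i <- runif(1, 50, 500)
    fr_i <- runif(sample(1:4, 1), 1, 100)
    base <- stability_ratio(ann_row(tgt_i, 20),
                            do.call(rbind, lapply(fr_i, ann_row, sn = 20,
                                                  label = "fragment")))$sr
    k <- runif(1, 0.1, 10)
    scaled <- stability_ratio(ann_row(k * tgt_i, 20),
                              do.call(rbind, lapply(k * fr_i, ann_row,
                                                    sn = 20,
                                                    label = "fragment")))$sr
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("replicate statistics follow the sample-sd definition", {
  expect_equal(replicate_stats(c(1, 1, 1)),
               list(mean = 1, sd = 0, rsd_percent = 0, n = 3L))
  st <- replicate_stats(c(2, 4))
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(st$rsd_percent, 100 * sqrt(2) / 3, tolerance = 1e-9)
  single <- replicate_stats(5)
  expect_true(is.na(single$sd))
  expect_true(is.na(single$rsd_percent))
  expect_error(replicate_stats(numeric(0)), "nonempty")
})

test_that("welch t-test matches the textbook formula", {
  a <- c(0.91, 0.85, 0.88, 0.95)
  b <- c(0.70, 0.78, 0.66)
  res <- welch_ttest(a, b)
  # hand computation of the Welch statistic and Welch-Satterthwaite df
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_two_sided, p_hand, tolerance = 1e-12)

  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)

  far <- welch_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(far$p_two_sided, 0.001)

  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("measured ratio divides intensities and enforces the SN gate", {
  mod <- ann_row(50, sn = 20, sequence = "GG[m6A]CU")
  unmod <- ann_row(100, sn = 30, sequence = "GGACU")
  expect_equal(measured_ratio(mod, unmod), 0.5)
  expect_equal(measured_ratio(unmod, unmod), 1.0)

  weak <- ann_row(100, sn = 9.9, sequence = "GGACU")
  expect_error(measured_ratio(mod, weak), "GGACU")
  expect_error(measured_ratio(mod, weak), "below quantification limit")
  weak_mod <- ann_row(50, sn = 2, sequence = "GG[m6A]CU")
  expect_error(measured_ratio(weak_mod, unmod), "GG\\[m6A\\]CU")

  # shared multiplicative spot factor cancels exactly
  expect_equal(measured_ratio(ann_row(50 * 7.3, 20), ann_row(100 * 7.3, 30)),
               0.5, tolerance = 1e-12)
})

test_that("calibration fit reproduces closed-form least squares", {
  exact <- data.frame(nominal_ratio = c(0.25, 0.5, 1, 2, 4),
                      measured_ratio = c(0.25, 0.5, 1, 2, 4))
  f1 <- fit_calibration(exact)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1)

  doubled <- transform(exact, measured_ratio = 2 * nominal_ratio)
  f2 <- fit_calibration(doubled)
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)

  # 5-point case vs normal equations computed directly here
  df <- data.frame(nominal_ratio = c(0.25, 0.5, 1, 2, 4),
                   measured_ratio = c(0.21, 0.55, 0.9, 2.2, 3.9))
  x <- df$nominal_ratio; y <- df$measured_ratio
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_hand <- mean(y) - slope_hand * mean(x)
  ss_res <- sum((y - int_hand - slope_hand * x)^2)
  r2_hand <- 1 - ss_res / sum((y - mean(y))^2)
  f3 <- fit_calibration(df)
  expect_equal(f3$slope, slope_hand, tolerance = 1e-12)
  expect_equal(f3$intercept, int_hand, tolerance = 1e-12)
  expect_equal(f3$r_squared, r2_hand, tolerance = 1e-12)

  # 2-point fit is exact interpolation
  two <- data.frame(nominal_ratio = c(1, 2), measured_ratio = c(1.1, 2.4))
  f4 <- fit_calibration(two)
  expect_equal(f4$slope, 1.3, tolerance = 1e-12)
  expect_equal(f4$intercept, -0.2, tolerance = 1e-12)
  expect_equal(f4$r_squared, 1)

  # forced-origin mode
  f5 <- fit_calibration(doubled, force_origin = TRUE)
  expect_equal(f5$slope, 2)
  expect_equal(f5$intercept, 0)

  expect_error(fit_calibration(data.frame(nominal_ratio = c(1, 1),
                                          measured_ratio = c(1, 1.1))),
               "distinct")
})

test_that("calibration accepts per-sample replicate lists", {
  samples <- list(
    list(nominal_ratio = 0.5, measured_ratios = c(0.48, 0.52)),
    list(nominal_ratio = 2, measured_ratios = c(1.9, 2.1, 2.0))
  )
  f <- fit_calibration(samples)
  expect_equal(f$n, 5L)
})

test_that("detection limits follow the 3x / 10x blank-noise rule", {
  dl <- detection_limits(blank_noise = 3, response_slope = 5)
  expect_equal(dl$lod_amount, 1.8)
  expect_equal(dl$loq_amount, 6.0)

  set.seed(71)
  for (i in 1:10) {
    noise <- runif(1, 0.1, 50); slope <- runif(1, 0.1, 100)
    dl <- detection_limits(noise, slope)
    expect_equal(dl$lod_amount, 3 * noise / slope, tolerance = 1e-12)
    expect_equal(dl$loq_amount / dl$lod_amount, 10 / 3, tolerance = 1e-12)
  }
  # strong response drives the LOD toward zero
  expect_lt(detection_limits(3, 1e9)$lod_amount, 1e-8)
  expect_error(detection_limits(0, 5), "> 0")
  expect_error(detection_limits(3, -1), "> 0")

  # accepts a noise_estimate object directly
  ne <- estimate_noise(NULL, method = "supplied", level = 3)
  expect_equal(detection_limits(ne, 5)$lod_amount, 1.8)
})
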