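test_that("generated trees are deterministic and internally consistent", {
  cfg <- synthetic_config()
  t1 <- generate_tree(cfg, seed = 5)
  t2 <- generate_tree(cfg, seed = 5)
  expect_identical(t1$whorls, t2$whorls)
  expect_identical(t1$branches$dry_mass_g, t2$branches$dry_mass_g)

  # pipe-model conservation holds exactly in the generative truth
  expect_lt(max(abs(cumsum(t1$whorls$basal_area_cm2) -
                      cfg$structure$eta * t1$whorls$stem_area_cm2)), 1e-6)
  expect_true(all(t1$whorls$whorl_height_m >= t1$metrics$crown_base_m))
  expect_true(all(diff(t1$whorls$whorl_height_m) < 0))
})

test_that("zero-noise closed loop recovers the generative truth", {
  cfg <- synthetic_config(biomass_log_sd = 0, height_jitter_sd = 0,
                          retention_intercept = 50, retention_slope = 0)
  tr <- generate_tree(cfg, seed = 7)
  det <- simulate_detections(tr, cfg, seed = 1)
  expect_equal(nrow(det), nrow(tr$branches))  # full retention
  expect_equal(sort(det$branch_height_m), sort(tr$branch_heights_m))

  est <- estimate_tree(tr$metrics, generate_slices(tr), det$branch_height_m,
                       run_config(seed = tr$pipeline_seed))
  expect_equal(nrow(est$prediction$whorls), nrow(tr$whorls))
  expect_lt(max(abs(est$prediction$whorls$basal_area_cm2 -
                      tr$whorls$basal_area_cm2)), 1e-6)
  expect_equal(est$prediction$whorls$n_branches, tr$whorls$n_branches)
  expect_lt(abs(est$totals_kg[["tsm_tls"]] - tr$total_kg), 1e-6)
})

test_that("omission extremes behave as specified", {
  cfg_none <- synthetic_config(retention_intercept = 50,
                               retention_slope = 0, height_jitter_sd = 0)
  tr <- generate_tree(cfg_none, seed = 3)
  det <- simulate_detections(tr, cfg_none, seed = 2)
  expect_equal(det$branch_height_m, sort(tr$branch_heights_m))

  cfg_all <- synthetic_config(retention_intercept = -50,
                              retention_slope = 0)
  det0 <- simulate_detections(tr, cfg_all, seed = 2)
  expect_equal(nrow(det0), 0L)
})

test_that("realized omission rates respect binomial bounds by crown layer", {
  # constant retention: realized rate within 99% binomial bounds
  p_const <- 0.35
  cfg_const <- synthetic_config(retention_intercept = qlogis(p_const),
                                retention_slope = 0, height_jitter_sd = 0)
  tot <- kept <- 0
  for (s in 1:10) {
    tr <- generate_tree(cfg_const, seed = 100 + s)
    det <- simulate_detections(tr, cfg_const, seed = 200 + s)
    tot <- tot + nrow(tr$branches)
    kept <- kept + nrow(det)
  }
  expect_gt(tot, 1000)
  bounds <- qbinom(c(0.005, 0.995), tot, p_const)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])

  # height-dependent default: omission decreases from treetop downward
  cfg <- synthetic_config(height_jitter_sd = 0)
  kept_up <- tot_up <- kept_lo <- tot_lo <- 0
  for (s in 1:10) {
    tr <- generate_tree(cfg, seed = 100 + s)
    det <- simulate_detections(tr, cfg, seed = 200 + s)
    lay_all <- crown_layer_of(pmin(pmax(
      relative_height(tr$branch_heights_m, tr$metrics), 0), 1))
    lay_det <- crown_layer_of(pmin(pmax(
      relative_height(det$branch_height_m, tr$metrics), 0), 1))
    tot_up <- tot_up + sum(lay_all == "upper")
    kept_up <- kept_up + sum(lay_det == "upper")
    tot_lo <- tot_lo + sum(lay_all == "lower")
    kept_lo <- kept_lo + sum(lay_det == "lower")
  }
  p_up <- kept_up / tot_up; p_lo <- kept_lo / tot_lo
  expect_lt(p_up, 0.55)  # upper-crown omission around 60%
  expect_gt(p_lo, 0.65)  # lower-crown omission around 20%
  expect_gt(p_lo, p_up)
})

test_that("noise-free slices lie on the analytic taper and rebuild it", {
  cfg <- synthetic_config()
  tr <- generate_tree(cfg, seed = 9)
  sl <- generate_slices(tr, noise_sd_cm = 0)
  a <- whorltls:::analytic_taper_diameter(sl$height_m, tr$metrics, cfg$taper)
  expect_equal(sl$diameter_cm, a, tolerance = 1e-12)
  tc <- build_taper_curve(sl, tr$metrics)
  q <- seq(1.3, tr$metrics$height_m, length.out = 80)
  expect_lt(max(abs(stem_diameter_at(tc, q) -
                      whorltls:::analytic_taper_diameter(q, tr$metrics,
                                                         cfg$taper))),
            0.005 * tr$metrics$dbh_cm)
  # noisy slices are deterministic under seed
  s1 <- generate_slices(tr, noise_sd_cm = 0.5, seed = 4)
  s2 <- generate_slices(tr, noise_sd_cm = 0.5, seed = 4)
  expect_identical(s1, s2)
})

test_that("heavier omission never reduces expected whorl omissions", {
  cfg_lo <- synthetic_config(retention_intercept = 1.5,
                             retention_slope = 0, height_jitter_sd = 0)
  cfg_hi <- synthetic_config(retention_intercept = -0.5,
                             retention_slope = 0, height_jitter_sd = 0)
  miss_lo <- miss_hi <- 0
  for (s in 1:15) {
    tr <- generate_tree(cfg_lo, seed = 300 + s)
    d_lo <- simulate_detections(tr, cfg_lo, seed = 400 + s)
    d_hi <- simulate_detections(tr, cfg_hi, seed = 400 + s)
    miss_lo <- miss_lo + (nrow(tr$branches) - nrow(d_lo))
    miss_hi <- miss_hi + (nrow(tr$branches) - nrow(d_hi))
  }
  expect_gt(miss_hi, miss_lo)
})

test_that("branch biomass increases with DBH at fixed height and crown ratio", {
  cfg <- synthetic_config(biomass_log_sd = 0)
  totals <- sapply(c(24, 30, 36, 42), function(D) {
    cfg2 <- synthetic_config(height_range = c(26, 26), dbh_range = c(D, D),
                             crown_ratio_range = c(0.4, 0.4),
                             biomass_log_sd = 0)
    generate_tree(cfg2, seed = 55)$total_kg
  })
  expect_true(all(diff(totals) > 0))
})
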