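test_that("crown layers partition relative height", {
  expect_equal(crown_layer_of(0), "upper")
  expect_equal(crown_layer_of(0.3), "middle")
  expect_equal(crown_layer_of(0.95), "lower")
  expect_equal(crown_layer_of(c(0.29, 0.69, 0.7, 1)),
               c("upper", "middle", "lower", "lower"))
  expect_error(crown_layer_of(1.2), "0, 1")
})

test_that("whorl pairing is one-to-one with correct leftover counts", {
  ident <- data.frame(height_m = 1:5, area_cm2 = c(5, 10, 20, 40, 80))
  pw <- pair_whorls(ident, ident)
  expect_equal(pw$counts$n_paired, 5L)
  expect_equal(pw$counts$n_commission, 0L)
  expect_equal(pw$counts$n_omission, 0L)
  expect_equal(pw$pairs$area_diff_cm2, rep(0, 5))

  ref <- data.frame(height_m = c(10, 8), area_cm2 = c(10, 20))
  est <- data.frame(height_m = 9.5, area_cm2 = 11)
  pw2 <- pair_whorls(ref, est)
  expect_equal(pw2$pairs$ref_idx, 1L)  # 10 is closer to 11 than 20
  expect_equal(pw2$counts$n_omission, 1L)
  expect_equal(pw2$counts$n_commission, 0L)

  none <- data.frame(height_m = numeric(0), area_cm2 = numeric(0))
  est3 <- data.frame(height_m = 1:3, area_cm2 = c(1, 2, 3))
  pw3 <- pair_whorls(none, est3)
  expect_equal(pw3$counts$n_paired, 0L)
  expect_equal(pw3$counts$n_commission, 3L)
})

test_that("pairing count identities hold on random instances", {
  set.seed(13)
  for (k in 1:20) {
    nr <- sample(0:5, 1); ne <- sample(0:5, 1)
    ref <- data.frame(height_m = seq_len(nr), area_cm2 = runif(nr, 1, 50))
    est <- data.frame(height_m = seq_len(ne), area_cm2 = runif(ne, 1, 50))
    pw <- pair_whorls(ref, est)
    expect_equal(pw$counts$n_paired + pw$counts$n_commission, ne)
    expect_equal(pw$counts$n_paired + pw$counts$n_omission, nr)
    # one-to-one: no index reused
    expect_false(any(duplicated(pw$pairs$ref_idx)))
    expect_false(any(duplicated(pw$pairs$est_idx)))
    # brute-force count oracle (counts depend only on set sizes)
    bf <- brute_pair_counts(ref$area_cm2, est$area_cm2)
    expect_equal(unname(pw$counts$n_paired), unname(bf["np"]))
  }
})

test_that("branch pairing within a whorl follows the count rule", {
  expect_equal(unlist(pair_branches_within_whorl(4, 4)[1:3]),
               c(n_paired = 4L, n_commission = 0L, n_omission = 0L))
  expect_equal(unlist(pair_branches_within_whorl(5, 3)[1:3]),
               c(n_paired = 3L, n_commission = 0L, n_omission = 2L))
  for (nr in 0:6) for (ne in 0:6) {
    cc <- pair_branches_within_whorl(nr, ne)
    expect_equal(cc$n_paired + cc$n_commission + cc$n_omission, max(nr, ne))
  }
})

test_that("detection metrics reproduce the published worked examples", {
  m <- detection_metrics(detection_counts(198, 71, 74))
  expect_equal(round(m$accuracy_pct, 2), 57.73)
  expect_equal(round(m$ec_pct, 2), 20.70)
  expect_equal(round(m$eo_pct, 2), 21.57)

  m11 <- detection_metrics(detection_counts(26, 3, 6))
  expect_equal(round(m11$accuracy_pct, 2), 74.29)

  perfect <- detection_metrics(detection_counts(10, 0, 0))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$ec_pct, 0)
  expect_error(detection_metrics(detection_counts(0, 0, 0)), "undefined")
})

test_that("accuracy, commission and omission always sum to 100", {
  set.seed(5)
  for (k in 1:25) {
    cc <- detection_counts(sample(0:50, 1), sample(0:30, 1), sample(0:30, 1))
    if (cc$n_paired + cc$n_commission + cc$n_omission == 0) next
    m <- detection_metrics(cc)
    expect_equal(m$accuracy_pct + m$ec_pct + m$eo_pct, 100,
                 tolerance = 1e-9)
  }
})

test_that("published count rows recompute their printed percentages", {
  counts <- detection_count_table()
  recomputed <- t(vapply(seq_len(nrow(counts)), function(i) {
    m <- detection_metrics(detection_counts(counts$n_p[i], counts$n_c[i],
                                            counts$n_o[i]))
    c(m$accuracy_pct, m$ec_pct, m$eo_pct)
  }, numeric(3)))
  printed <- as.matrix(counts[c("accuracy_pct", "ec_pct", "eo_pct")])
  consistent <- abs(rowSums(printed) - 100) < 0.05
  # the published table is self-consistent in all but two rows
  expect_gte(sum(consistent), nrow(counts) - 2)
  expect_true(all(abs(round(recomputed[consistent, ], 2) -
                        printed[consistent, ]) < 0.006))
  # accuracy recomputes to the printed two decimals in every row
  expect_true(all(abs(round(recomputed[, 1], 2) -
                        printed[, "accuracy_pct"]) < 0.006))
})

test_that("RMSE and CV-RMSE follow their definitions", {
  expect_equal(unlist(rmse_cv(c(1, 2, 3), c(1, 2, 3))), c(rmse = 0,
                                                          cv_rmse_pct = 0))
  r <- rmse_cv(c(3, 3), c(1, 1))
  expect_equal(r$rmse, 2)
  expect_equal(r$cv_rmse_pct, 200)
  set.seed(8)
  m <- runif(10, 1, 5); f <- runif(10, 1, 5)
  r1 <- rmse_cv(m, f); r2 <- rmse_cv(3 * m, 3 * f)
  expect_equal(r2$rmse, 3 * r1$rmse)
  expect_equal(r2$cv_rmse_pct, r1$cv_rmse_pct)
  expect_error(rmse_cv(1:3, 1:2), "length")
})

test_that("concordance correlation matches its closed form", {
  expect_equal(concordance_ccc(1:10, 1:10), 1)
  x <- c(-2, 0, 2)
  expect_equal(concordance_ccc(x, -x), -1)
  expect_equal(concordance_ccc(c(1, 2, 3), c(2, 3, 5)), 0.5)
  # |CCC| <= |Pearson|, equality iff means and variances agree
  set.seed(17)
  for (k in 1:10) {
    a <- rnorm(20); b <- 2 * a + rnorm(20, 1, 0.5)
    expect_lte(abs(concordance_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(concordance_ccc(rep(1, 5), rep(2, 5)), "constant")
})

test_that("KS comparison matches brute-force ECDF enumeration", {
  expect_equal(ks_ecdf_compare(1:20, 1:20)$D, 0)
  expect_equal(ks_ecdf_compare(c(0, 0, 0), c(1, 1, 1))$D, 1)
  expect_equal(ks_ecdf_compare(c(1, 2), c(1.5, 2.5))$D, 0.5)
  # brute-force sup over the pooled sample against the stats route
  set.seed(23)
  for (k in 1:10) {
    a <- rnorm(15); b <- rnorm(12, 0.5)
    grid <- sort(c(a, b))
    sup <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(ks_ecdf_compare(a, b)$D, sup, tolerance = 1e-12)
  }
  expect_error(ks_ecdf_compare(numeric(0), 1:3), "non-empty")
})

test_that("identical estimate and reference yield perfect metrics everywhere", {
  tm <- tree_metrics(25, 30, 15)
  wh <- data.frame(height_m = c(24.6, 23.0, 21.0, 19.0, 17.0, 15.4),
                   area_cm2 = c(2, 20, 60, 120, 200, 290),
                   n_branches = c(2, 3, 4, 5, 5, 6))
  br <- data.frame(whorl_height_m = rep(wh$height_m, wh$n_branches),
                   diameter_mm = unlist(lapply(wh$n_branches,
                                               function(n) 10 + seq_len(n))))
  br$dry_mass_g <- 0.05 * br$diameter_mm^2.3
  side <- list(whorls = wh, branches = br)
  rep_ <- evaluate_tree(side, side, tm)
  expect_true(all(rep_$whorl$accuracy_pct == 100))
  expect_true(all(rep_$branch$accuracy_pct == 100))
  expect_true(all(rep_$diameter$mean_rel_err_pct == 0))
  expect_true(all(rep_$diameter$rmse_mm == 0))
  expect_true(all(rep_$ks$D == 0))
})

test_that("stratum counts partition the whole-tree counts", {
  tm <- tree_metrics(25, 30, 15)
  set.seed(29)
  mk <- function(n) {
    h <- sort(runif(n, 15.2, 24.8), decreasing = TRUE)
    data.frame(height_m = h, area_cm2 = (25 - h)^2 * 3,
               n_branches = sample(1:6, n, replace = TRUE))
  }
  ref <- list(whorls = mk(12)); est <- list(whorls = mk(9))
  rep_ <- evaluate_tree(est, ref, tm)
  for (tab in list(rep_$whorl, rep_$branch)) {
    whole <- tab[tab$stratum == "whole", ]
    parts <- tab[tab$stratum != "whole", ]
    expect_equal(sum(parts$n_paired), whole$n_paired)
    expect_equal(sum(parts$n_commission), whole$n_commission)
    expect_equal(sum(parts$n_omission), whole$n_omission)
  }

  # one extra reference whorl increments omissions by exactly one
  ref2 <- list(whorls = rbind(ref$whorls,
                              data.frame(height_m = 15.05, area_cm2 = 500,
                                         n_branches = 4)))
  rep2 <- evaluate_tree(est, ref2, tm)
  expect_equal(rep2$whorl$n_omission[rep2$whorl$stratum == "whole"],
               rep_$whorl$n_omission[rep_$whorl$stratum == "whole"] + 1L)

  expect_warning(expect_null(
    evaluate_tree(est, list(whorls = NULL), tm)), "skipped")
})
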