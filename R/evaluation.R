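#' Crown layer of a relative height
#'
#' Stratifies the crown into upper (`h_r < 0.3`), middle
#' (`0.3 <= h_r < 0.7`) and lower (`h_r >= 0.7`) layers.
#'
#' @param h_r Relative height(s) in the crown, in `[0, 1]`.
#' @return Character vector: `"upper"`, `"middle"` or `"lower"`.
#' @examples
#' crown_layer_of(c(0, 0.3, 0.95))
#' @export
crown_layer_of <- function(h_r) {
  if (any(h_r < -1e-9 | h_r > 1 + 1e-9)) stop("h_r must lie in [0, 1]")
  out <- rep("lower", length(h_r))
  out[h_r < 0.7] <- "middle"
  out[h_r < 0.3] <- "upper"
  out
}

#' Pair estimated with reference whorls by stem cross-sectional area
#'
#' One-to-one greedy matching: the globally closest pair by absolute
#' stem-area difference is matched first, repeatedly, until one side is
#' exhausted. Unmatched estimated whorls are commissions; unmatched
#' reference whorls are omissions.
#'
#' @param ref data.frame of reference whorls with columns `height_m`
#'   and `area_cm2`.
#' @param est data.frame of estimated whorls, same columns.
#' @return A list with `pairs` (data.frame `ref_idx`, `est_idx`,
#'   `area_diff_cm2`) and `counts` (list `n_paired`, `n_commission`,
#'   `n_omission`).
#' @export
pair_whorls <- function(ref, est) {
  stopifnot(is.data.frame(ref), is.data.frame(est))
  for (nm in list(ref, est))
    if (nrow(nm) && !all(c("height_m", "area_cm2") %in% names(nm)))
      stop("whorl tables need columns height_m and area_cm2")
  if (nrow(ref) && any(ref$area_cm2 < 0)) stop("areas must be non-negative")
  if (nrow(est) && any(est$area_cm2 < 0)) stop("areas must be non-negative")
  nr <- nrow(ref); ne <- nrow(est)
  pairs <- data.frame(ref_idx = integer(0), est_idx = integer(0),
                      area_diff_cm2 = numeric(0))
  if (nr > 0 && ne > 0) {
    diff_mat <- abs(outer(ref$area_cm2, est$area_cm2, "-"))
    repeat {
      m <- which(diff_mat == min(diff_mat), arr.ind = TRUE)
      # deterministic tie-break: lowest reference index, then estimate index
      m <- m[order(m[, 1], m[, 2]), , drop = FALSE][1, ]
      pairs <- rbind(pairs, data.frame(ref_idx = m[1], est_idx = m[2],
                                       area_diff_cm2 = diff_mat[m[1], m[2]]))
      diff_mat[m[1], ] <- Inf
      diff_mat[, m[2]] <- Inf
      if (nrow(pairs) == min(nr, ne)) break
    }
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       counts = detection_counts(n_paired = nrow(pairs),
                                 n_commission = ne - nrow(pairs),
                                 n_omission = nr - nrow(pairs)))
}

#' Detection counts
#'
#' @param n_paired Number of paired whorls/branches.
#' @param n_commission Falsely detected or modelled items.
#' @param n_omission Items missed relative to the reference.
#' @return A list of class `detection_counts`.
#' @export
detection_counts <- function(n_paired, n_commission, n_omission) {
  stopifnot(n_paired >= 0, n_commission >= 0, n_omission >= 0)
  structure(list(n_paired = as.integer(n_paired),
                 n_commission = as.integer(n_commission),
                 n_omission = as.integer(n_omission)),
            class = "detection_counts")
}

#' Branch pairing within a matched whorl
#'
#' Branches inside a paired whorl are matched by count:
#' `N_p = min(n_ref, n_est)`, the surplus on the estimated side is
#' commission and on the reference side omission.
#'
#' @param n_ref Reference branch count (>= 0).
#' @param n_est Estimated branch count (>= 0).
#' @return A `detection_counts` object.
#' @examples
#' pair_branches_within_whorl(5, 3)  # 3 paired, 0 commission, 2 omission
#' @export
pair_branches_within_whorl <- function(n_ref, n_est) {
  stopifnot(n_ref >= 0, n_est >= 0)
  detection_counts(min(n_ref, n_est), max(0, n_est - n_ref),
                   max(0, n_ref - n_est))
}

#' Accuracy, commission and omission percentages
#'
#' All three share the denominator `N_p + N_c + N_o`, so they sum to
#' 100 %.
#'
#' @param counts A `detection_counts` object.
#' @return A list with `accuracy_pct`, `ec_pct`, `eo_pct`.
#' @examples
#' detection_metrics(detection_counts(198, 71, 74))
#' @export
detection_metrics <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  tot <- counts$n_paired + counts$n_commission + counts$n_omission
  if (tot == 0) stop("detection metrics undefined for all-zero counts")
  list(accuracy_pct = 100 * counts$n_paired / tot,
       ec_pct = 100 * counts$n_commission / tot,
       eo_pct = 100 * counts$n_omission / tot)
}

#' RMSE and CV-RMSE against a reference
#'
#' @param model_values Model predictions.
#' @param ref_values Reference values, same length, non-zero mean for
#'   the CV.
#' @return A list with `rmse` (reference units) and `cv_rmse_pct`
#'   (percent of the reference mean).
#' @examples
#' rmse_cv(c(3, 3), c(1, 1))  # rmse 2, cv 200
#' @export
rmse_cv <- function(model_values, ref_values) {
  m <- as.numeric(model_values); r <- as.numeric(ref_values)
  if (length(m) != length(r)) stop("vectors differ in length")
  if (length(m) < 1L) stop("at least one pair is required")
  rmse <- sqrt(mean((m - r)^2))
  mr <- mean(r)
  cv <- if (abs(mr) < .Machine$double.eps) NA_real_ else 100 * rmse / mr
  list(rmse = rmse, cv_rmse_pct = cv)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments.
#'
#' @param x,y Paired numeric vectors, length >= 2, not both constant.
#' @return CCC in `[-1, 1]`.
#' @examples
#' concordance_ccc(c(1, 2, 3), c(2, 3, 5))  # 0.5
#' @export
concordance_ccc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors differ in length")
  n <- length(x)
  if (n < 2L) stop("at least two pairs are required")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 < .Machine$double.eps && sy2 < .Machine$double.eps)
    stop("CCC undefined: both vectors constant")
  den <- sx2 + sy2 + (mx - my)^2
  2 * sxy / den
}

#' Two-sample Kolmogorov-Smirnov comparison of ECDFs
#'
#' Maximum vertical distance between the two empirical cumulative
#' distribution functions, with the asymptotic two-sample p-value.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A list with `D` and `p_value`.
#' @examples
#' ks_ecdf_compare(c(1, 2), c(1.5, 2.5))  # D = 0.5
#' @export
ks_ecdf_compare <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Evaluate estimated whorl structure against a reference
#'
#' Pairs whorls by stem cross-sectional area, counts branch matches
#' within paired whorls, and reports accuracy/commission/omission per
#' crown stratum (whole tree, upper, middle, lower). Paired whorls are
#' assigned to strata by the reference whorl's relative height;
#' unmatched reference whorls (omissions) by their own height;
#' unmatched estimated whorls (commissions) by the estimate's height --
#' so stratum counts sum exactly to the whole-tree counts. When both
#' tables carry branch diameters, rank-matched (largest-to-largest)
#' relative diameter errors are reported per stratum, and when both
#' carry branch masses a KS comparison per stratum is added.
#'
#' @param est Estimated tree: list with `whorls` (data.frame
#'   `height_m`, `area_cm2`, `n_branches`) and optionally `branches`
#'   (data.frame `whorl_height_m`, `diameter_mm`, optional
#'   `dry_mass_g`).
#' @param ref Reference (destructive) measurement, same structure.
#' @param tree A [tree_metrics()] object.
#' @return A list with data.frames `whorl` and `branch` (stratum-level
#'   detection metrics), `diameter` (stratum mean relative errors and
#'   RMSE, if available) and `ks` (stratum D and p on branch mass, if
#'   available).
#' @export
evaluate_tree <- function(est, ref, tree) {
  stopifnot(inherits(tree, "tree_metrics"))
  if (is.null(ref) || is.null(ref$whorls) || nrow(ref$whorls) == 0) {
    warning("no reference whorls supplied; evaluation skipped")
    return(NULL)
  }
  strata <- c("whole", "upper", "middle", "lower")
  layer_of_height <- function(h)
    crown_layer_of(pmin(pmax(relative_height(h, tree), 0), 1))

  pw <- pair_whorls(ref$whorls, est$whorls)
  pr <- pw$pairs
  ref_layer <- layer_of_height(ref$whorls$height_m)
  est_layer <- layer_of_height(est$whorls$height_m)
  om_idx <- setdiff(seq_len(nrow(ref$whorls)), pr$ref_idx)
  cm_idx <- setdiff(seq_len(nrow(est$whorls)), pr$est_idx)

  count_in <- function(layer) {
    inpair <- if (layer == "whole") rep(TRUE, nrow(pr))
              else ref_layer[pr$ref_idx] == layer
    om <- if (layer == "whole") om_idx else om_idx[ref_layer[om_idx] == layer]
    cm <- if (layer == "whole") cm_idx else cm_idx[est_layer[cm_idx] == layer]
    list(pairs = pr[inpair, , drop = FALSE],
         counts = detection_counts(sum(inpair), length(cm), length(om)))
  }

  whorl_rows <- list(); branch_rows <- list()
  for (layer in strata) {
    ci <- count_in(layer)
    cc <- ci$counts
    met <- if (cc$n_paired + cc$n_commission + cc$n_omission > 0)
      detection_metrics(cc) else list(accuracy_pct = NA_real_,
                                      ec_pct = NA_real_, eo_pct = NA_real_)
    whorl_rows[[layer]] <- data.frame(
      stratum = layer, n_paired = cc$n_paired,
      n_commission = cc$n_commission, n_omission = cc$n_omission,
      accuracy_pct = met$accuracy_pct, ec_pct = met$ec_pct,
      eo_pct = met$eo_pct)

    # branch counts within paired whorls of this stratum
    np <- nc <- no <- 0L
    if (nrow(ci$pairs)) {
      for (k in seq_len(nrow(ci$pairs))) {
        bc <- pair_branches_within_whorl(
          ref$whorls$n_branches[ci$pairs$ref_idx[k]],
          est$whorls$n_branches[ci$pairs$est_idx[k]])
        np <- np + bc$n_paired; nc <- nc + bc$n_commission
        no <- no + bc$n_omission
      }
    }
    bmet <- if (np + nc + no > 0)
      detection_metrics(detection_counts(np, nc, no))
    else list(accuracy_pct = NA_real_, ec_pct = NA_real_, eo_pct = NA_real_)
    branch_rows[[layer]] <- data.frame(
      stratum = layer, n_paired = np, n_commission = nc, n_omission = no,
      accuracy_pct = bmet$accuracy_pct, ec_pct = bmet$ec_pct,
      eo_pct = bmet$eo_pct)
  }

  out <- list(whorl = do.call(rbind, whorl_rows),
              branch = do.call(rbind, branch_rows))
  rownames(out$whorl) <- rownames(out$branch) <- NULL

  # rank-matched diameter comparison within paired whorls
  if (!is.null(est$branches) && !is.null(ref$branches) &&
      nrow(est$branches) && nrow(ref$branches)) {
    de <- dr <- hr <- numeric(0)
    for (k in seq_len(nrow(pr))) {
      rh <- ref$whorls$height_m[pr$ref_idx[k]]
      eh <- est$whorls$height_m[pr$est_idx[k]]
      rb <- sort(ref$branches$diameter_mm[
        abs(ref$branches$whorl_height_m - rh) < 1e-6], decreasing = TRUE)
      eb <- sort(est$branches$diameter_mm[
        abs(est$branches$whorl_height_m - eh) < 1e-6], decreasing = TRUE)
      m <- min(length(rb), length(eb))
      if (m > 0) {
        de <- c(de, eb[seq_len(m)]); dr <- c(dr, rb[seq_len(m)])
        hr <- c(hr, rep(min(max(relative_height(rh, tree), 0), 1), m))
      }
    }
    if (length(dr)) {
      lay <- crown_layer_of(hr)
      diam_rows <- lapply(strata, function(layer) {
        sel <- if (layer == "whole") rep(TRUE, length(dr)) else lay == layer
        if (!any(sel)) return(data.frame(
          stratum = layer, n = 0L, mean_rel_err_pct = NA_real_,
          rmse_mm = NA_real_))
        rc <- rmse_cv(de[sel], dr[sel])
        data.frame(stratum = layer, n = sum(sel),
                   mean_rel_err_pct =
                     mean(100 * abs(de[sel] - dr[sel]) / dr[sel]),
                   rmse_mm = rc$rmse)
      })
      out$diameter <- do.call(rbind, diam_rows)
    }
  }

  # KS comparison of branch dry-mass distributions per stratum
  if (!is.null(est$branches) && !is.null(ref$branches) &&
      !is.null(est$branches$dry_mass_g) && !is.null(ref$branches$dry_mass_g) &&
      nrow(est$branches) && nrow(ref$branches)) {
    hr_est <- pmin(pmax(relative_height(est$branches$whorl_height_m, tree),
                        0), 1)
    hr_ref <- pmin(pmax(relative_height(ref$branches$whorl_height_m, tree),
                        0), 1)
    le <- crown_layer_of(hr_est); lr <- crown_layer_of(hr_ref)
    ks_rows <- lapply(strata, function(layer) {
      a <- est$branches$dry_mass_g[layer == "whole" | le == layer]
      b <- ref$branches$dry_mass_g[layer == "whole" | lr == layer]
      if (!length(a) || !length(b))
        return(data.frame(stratum = layer, D = NA_real_,
                          p_value = NA_real_))
      ks <- ks_ecdf_compare(a, b)
      data.frame(stratum = layer, D = ks$D, p_value = ks$p_value)
    })
    out$ks <- do.call(rbind, ks_rows)
  }
  out
}
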