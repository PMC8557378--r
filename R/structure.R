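#' Tree structure model parameters
#'
#' Fixed-effect parameter set for the whorl structure models: the
#' pipe-model coefficient `eta` linking cumulative branch basal area to
#' stem cross-sectional area, the branch-count regression, and the
#' log-scale models for the relative sizes of the largest and smallest
#' branch in a whorl. Defaults are the fixed-part estimates fitted to the
#' VAPU destructive database of 122 Scots pines (random effects are never
#' applied in prediction).
#'
#' @param eta Pipe-model proportionality coefficient (dimensionless, > 0).
#' @param m1 Branch-count coefficients `c(b0, b1, b2, b3)` multiplying
#'   `1, ln(delta_h_cm), (H - 1.3)/DBH, h_r`.
#' @param m3max Largest-branch coefficients `c(b0..b5)` multiplying
#'   `1, N_bi, (1.1 - h_r), ln(1.1 - h_r), DBH, H/DBH` on the log scale.
#' @param m3min Smallest-branch coefficients `c(b0..b4)` multiplying
#'   `1, N_bi, (1.1 - h_r), ln(1.1 - h_r), DBH` on the logit scale.
#' @param eta_in_eq3 Apply `eta` when converting stem-area increments to
#'   whorl basal area (the variant consistent with the telescoping
#'   pipe-model sum; see Details).
#'
#' @details The whorl basal-area increment is
#' `B_i = eta * (A_i - A_above)`. With `eta_in_eq3 = FALSE` the increment
#' is used without `eta`, which breaks the telescoping identity
#' `sum(B_j, j <= i) = eta * A_i`; the flag exists because the increment
#' form is sometimes printed without the coefficient.
#'
#' @return An object of class `structure_params`.
#' @examples
#' structure_params()
#' @export
structure_params <- function(eta = 1.810,
                             m1 = c(1.514, 0.883, -0.712, -0.405),
                             m3max = c(0.237, 0.079, -0.277, 0.036, 0.001,
                                       -0.007),
                             m3min = c(0.894, -0.412, 1.404, -0.214, -0.004),
                             eta_in_eq3 = TRUE) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0,
            length(m1) == 4L, length(m3max) == 6L, length(m3min) == 5L,
            is.logical(eta_in_eq3))
  structure(list(eta = eta, m1 = as.numeric(m1), m3max = as.numeric(m3max),
                 m3min = as.numeric(m3min), eta_in_eq3 = eta_in_eq3),
            class = "structure_params")
}

#' @export
print.structure_params <- function(x, ...) {
  cat("Structure model parameters (fixed part)\n")
  cat(sprintf("  eta = %.3f%s\n", x$eta,
              if (x$eta_in_eq3) "" else " (not applied to increments)"))
  cat("  branch count:", paste(format(x$m1), collapse = ", "), "\n")
  cat("  largest-branch:", paste(format(x$m3max), collapse = ", "), "\n")
  cat("  smallest-branch:", paste(format(x$m3min), collapse = ", "), "\n")
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Predict the number of branches in a whorl
#'
#' Linear fixed-part model on the height increment to the whorl above,
#' tree slenderness and relative crown height; the raw prediction is
#' rounded half-up and clamped to at least one branch.
#'
#' @param delta_h_cm Height increment (cm) between this whorl and the one
#'   above (treetop for the topmost whorl); must be positive (floor small
#'   increments at 1 cm before calling).
#' @param tree A [tree_metrics()] object.
#' @param h_r Relative height in the crown, in `[0, 1]`.
#' @param params A [structure_params()] object.
#' @return Integer branch count >= 1.
#' @examples
#' predict_branch_count(50, tree_metrics(25, 30, 15), 0.5)  # 4
#' @export
predict_branch_count <- function(delta_h_cm, tree, h_r,
                                 params = structure_params()) {
  stopifnot(inherits(tree, "tree_metrics"),
            inherits(params, "structure_params"))
  if (any(delta_h_cm <= 0)) stop("delta_h_cm must be positive")
  if (any(h_r < -1e-9 | h_r > 1 + 1e-9)) stop("h_r must lie in [0, 1]")
  b <- params$m1
  raw <- b[1] + b[2] * log(delta_h_cm) +
    b[3] * (tree$height_m - 1.3) / tree$dbh_cm + b[4] * h_r
  as.integer(pmax(1, round_half_up(raw)))
}

#' Whorl total branch basal area from the pipe model
#'
#' By pipe model theory the cumulative branch basal area at and above a
#' whorl is proportional (coefficient `eta`) to the stem cross-sectional
#' area at the whorl, so the whorl's own share is the between-whorl
#' increment `eta * (A_i - A_above)`, clamped at zero. `A_above` is the
#' stem area at the whorl immediately above (0 for the topmost whorl).
#'
#' @param a_i_cm2 Stem cross-sectional area at the whorl (cm^2).
#' @param a_above_cm2 Stem area at the whorl above (cm^2), 0 for topmost.
#' @param params A [structure_params()] object.
#' @return Whorl branch basal area (cm^2).
#' @examples
#' whorl_basal_area(10, 0)  # 18.10
#' @export
whorl_basal_area <- function(a_i_cm2, a_above_cm2,
                             params = structure_params()) {
  stopifnot(inherits(params, "structure_params"))
  if (any(a_i_cm2 < 0) || any(a_above_cm2 < 0))
    stop("stem areas must be non-negative")
  inc <- pmax(a_i_cm2 - a_above_cm2, 0)
  if (params$eta_in_eq3) params$eta * inc else inc
}

#' Relative sizes of the largest and smallest branch in a whorl
#'
#' The largest and smallest branch basal areas, expressed relative to the
#' whorl mean, are predicted from branch count, relative crown depth and
#' tree dimensions: log-linear for the maximum (clamped to >= 1) and
#' logit-linear for the minimum (in (0, 1)).
#'
#' @param n_bi Branch count in the whorl (>= 1).
#' @param h_r Relative height in the crown, must satisfy `h_r <= 1.1`.
#' @param tree A [tree_metrics()] object.
#' @param params A [structure_params()] object.
#' @return A list with `r_max` (>= 1) and `r_min` (in (0, 1)).
#' @examples
#' relative_extremes(5, 0.5, tree_metrics(25, 30, 15))
#' @export
relative_extremes <- function(n_bi, h_r, tree, params = structure_params()) {
  stopifnot(inherits(tree, "tree_metrics"),
            inherits(params, "structure_params"))
  if (any(n_bi < 1)) stop("n_bi must be at least 1")
  if (any(h_r > 1.1 - 1e-12)) stop("h_r too large: 1.1 - h_r must be positive")
  u <- 1.1 - h_r
  bx <- params$m3max
  r_max <- exp(bx[1] + bx[2] * n_bi + bx[3] * u + bx[4] * log(u) +
                 bx[5] * tree$dbh_cm + bx[6] * tree$height_m / tree$dbh_cm)
  r_max <- pmax(r_max, 1)
  bn <- params$m3min
  x <- bn[1] + bn[2] * n_bi + bn[3] * u + bn[4] * log(u) + bn[5] * tree$dbh_cm
  r_min <- stats::plogis(x)
  list(r_max = r_max, r_min = r_min)
}

#' Sample individual branch basal areas within a whorl
#'
#' Individual relative branch sizes are drawn from a uniform distribution
#' constrained by the whorl's relative extremes, then rescaled
#' multiplicatively so the basal areas sum exactly to the whorl total.
#' A single-branch whorl receives the whole whorl basal area.
#'
#' @param b_i_cm2 Whorl total branch basal area (cm^2, > 0).
#' @param n_bi Number of branches (>= 1).
#' @param r_max,r_min Relative size constraints, `r_min <= 1 <= r_max`.
#' @param rng_seed Optional integer seed; when supplied the draw is
#'   deterministic and the caller's RNG state is left untouched.
#' @return Numeric vector of `n_bi` basal areas summing to `b_i_cm2`.
#' @examples
#' sample_branch_sizes(30, 6, r_max = 1.6, r_min = 0.4, rng_seed = 1)
#' @export
sample_branch_sizes <- function(b_i_cm2, n_bi, r_max, r_min,
                                rng_seed = NULL) {
  stopifnot(b_i_cm2 > 0, n_bi >= 1)
  if (r_min > r_max) stop("r_min must not exceed r_max")
  n_bi <- as.integer(n_bi)
  if (n_bi == 1L) return(b_i_cm2)
  draw <- function() {
    u <- stats::runif(n_bi, min = r_min, max = r_max)
    rel <- u * n_bi / sum(u)     # mean relative size rescaled to 1
    rel * b_i_cm2 / n_bi
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Convert branch basal area to diameter
#'
#' @param area_cm2 Basal area(s) in cm^2 (>= 0).
#' @return Diameter(s) in mm.
#' @examples
#' basal_area_to_diameter(pi / 4)  # 10 mm
#' @export
basal_area_to_diameter <- function(area_cm2) {
  if (any(area_cm2 < 0)) stop("basal area must be non-negative")
  2 * sqrt(area_cm2 / pi) * 10
}

#' Run the whorl structure pipeline
#'
#' Applies the structure models to a whorl series top-down: for each
#' whorl computes the height increment to the whorl above (treetop for
#' the topmost, floored at 1 cm), the relative crown height, the stem
#' cross-sectional area from the taper curve, the pipe-model whorl basal
#' area, the predicted branch count, the relative extremes, and finally
#' samples individual branch basal areas and diameters. Whorls with zero
#' basal-area increment carry zero branches.
#'
#' @param series A `whorl_series` (see [cluster_detections()]).
#' @param curve A `taper_curve` for the same tree.
#' @param params A [structure_params()] object.
#' @param rng_seed Integer seed controlling the uniform branch-size draws.
#' @return A list of class `whorl_prediction` with elements
#'   `whorls` (data.frame: whorl_index, whorl_height_m, is_fake,
#'   delta_h_cm, h_r, stem_area_cm2, basal_area_cm2, n_branches,
#'   r_max, r_min), `branches` (data.frame: whorl_index, branch_rank,
#'   basal_area_cm2, diameter_mm), `tree`, and `rng_seed`.
#' @export
run_structure_pipeline <- function(series, curve,
                                   params = structure_params(),
                                   rng_seed = 1L) {
  stopifnot(inherits(series, "whorl_series"), inherits(curve, "taper_curve"),
            inherits(params, "structure_params"))
  tree <- series$tree
  n <- length(series$height_m)
  empty <- list(
    tree = tree, rng_seed = rng_seed,
    whorls = data.frame(whorl_index = integer(0), whorl_height_m = numeric(0),
                        is_fake = logical(0), delta_h_cm = numeric(0),
                        h_r = numeric(0), stem_area_cm2 = numeric(0),
                        basal_area_cm2 = numeric(0), n_branches = integer(0),
                        r_max = numeric(0), r_min = numeric(0)),
    branches = data.frame(whorl_index = integer(0), branch_rank = integer(0),
                          basal_area_cm2 = numeric(0),
                          diameter_mm = numeric(0)))
  class(empty) <- "whorl_prediction"
  if (n == 0L) return(empty)

  hs <- series$height_m               # decreasing, index 1 = topmost
  above <- c(tree$height_m, hs[-n])
  delta_h <- pmax((above - hs) * 100, 1)  # cm, floored at 1
  h_r <- relative_height(hs, tree)
  a_i <- stem_area_at(curve, hs)
  a_above <- c(0, a_i[-n])

  res <- with_seed(rng_seed, {
    wl <- vector("list", n)
    bl <- vector("list", n)
    for (i in seq_len(n)) {
      b_i <- whorl_basal_area(a_i[i], a_above[i], params)
      if (b_i <= 0) {
        nb <- 0L; rmx <- NA_real_; rmn <- NA_real_
        areas <- numeric(0)
      } else {
        nb <- tryCatch(
          predict_branch_count(delta_h[i], tree, min(max(h_r[i], 0), 1),
                               params),
          error = function(e) stop("whorl ", i, ": ", conditionMessage(e)))
        ext <- relative_extremes(nb, min(max(h_r[i], 0), 1), tree, params)
        rmx <- ext$r_max; rmn <- ext$r_min
        areas <- sample_branch_sizes(b_i, nb, rmx, rmn)
      }
      wl[[i]] <- data.frame(
        whorl_index = i, whorl_height_m = hs[i], is_fake = series$is_fake[i],
        delta_h_cm = delta_h[i], h_r = h_r[i], stem_area_cm2 = a_i[i],
        basal_area_cm2 = b_i, n_branches = nb, r_max = rmx, r_min = rmn)
      if (length(areas)) {
        areas <- sort(areas, decreasing = TRUE)
        bl[[i]] <- data.frame(
          whorl_index = i, branch_rank = seq_along(areas),
          basal_area_cm2 = areas,
          diameter_mm = basal_area_to_diameter(areas))
      }
    }
    list(whorls = do.call(rbind, wl),
         branches = if (any(!vapply(bl, is.null, logical(1))))
           do.call(rbind, bl) else empty$branches)
  })
  out <- list(tree = tree, rng_seed = rng_seed, whorls = res$whorls,
              branches = res$branches)
  class(out) <- "whorl_prediction"
  out
}

#' @export
print.whorl_prediction <- function(x, ...) {
  cat(sprintf("Whorl predictions for tree '%s': %d whorls, %d branches (seed %d)\n",
              x$tree$tree_id, nrow(x$whorls), nrow(x$branches),
              as.integer(x$rng_seed)))
  invisible(x)
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
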