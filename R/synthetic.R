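#' Configuration for the synthetic tree generator
#'
#' Defines the study conditions emulated by the simulator: mature Scots
#' pine dimensions (heights 20-31 m, DBH 22-41 cm, crown ratios
#' 0.25-0.5), an analytic stem taper (cone or quadratic paraboloid),
#' annual whorl spacing around 0.30 m, the structure and biomass model
#' parameter sets, log-scale branch-mass noise matching the dry-mass
#' model's residual spread, and TLS detection defects (height jitter
#' and height-dependent omission, severe near the treetop).
#'
#' @param height_range,dbh_range,crown_ratio_range Uniform sampling
#'   ranges for tree height (m), DBH (cm) and crown length / height.
#' @param taper `"paraboloid"` (squared diameter linear in height, the
#'   default: it reproduces the crown-base diameters of mature pines
#'   far better than a cone) or `"cone"` (diameter linear in height);
#'   both are anchored at DBH and a zero-diameter treetop.
#' @param whorl_spacing_mean,whorl_spacing_sd Normal inter-whorl spacing
#'   (m), truncated to `[0.05, 0.5]`.
#' @param structure,biomass Parameter sets for the structure and biomass
#'   models ([structure_params()], [biomass_params()]).
#' @param biomass_log_sd Log-scale sd of multiplicative branch-mass
#'   noise; mean-corrected so expected mass equals the model value.
#' @param retention_intercept,retention_slope Logistic detection
#'   retention `plogis(a + b * h_r)`: defaults give about 60 % omission
#'   in the upper crown and about 20 % in the lower crown.
#' @param height_jitter_sd Gaussian sd (m) of detected branch heights.
#' @param slice_noise_sd_cm Gaussian sd of slice diameter errors (cm).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(height_range = c(20, 31),
                             dbh_range = c(22, 41),
                             crown_ratio_range = c(0.25, 0.5),
                             taper = c("paraboloid", "cone"),
                             whorl_spacing_mean = 0.30,
                             whorl_spacing_sd = 0.05,
                             structure = structure_params(),
                             biomass = biomass_params(),
                             biomass_log_sd = 0.43,
                             retention_intercept = -0.79,
                             retention_slope = 2.56,
                             height_jitter_sd = 0.01,
                             slice_noise_sd_cm = 0) {
  taper <- match.arg(taper)
  stopifnot(biomass_log_sd >= 0, height_jitter_sd >= 0,
            slice_noise_sd_cm >= 0, whorl_spacing_mean > 0,
            whorl_spacing_sd >= 0,
            inherits(structure, "structure_params"),
            inherits(biomass, "biomass_params"))
  structure(list(height_range = height_range, dbh_range = dbh_range,
                 crown_ratio_range = crown_ratio_range, taper = taper,
                 whorl_spacing_mean = whorl_spacing_mean,
                 whorl_spacing_sd = whorl_spacing_sd,
                 structure = structure, biomass = biomass,
                 biomass_log_sd = biomass_log_sd,
                 retention_intercept = retention_intercept,
                 retention_slope = retention_slope,
                 height_jitter_sd = height_jitter_sd,
                 slice_noise_sd_cm = slice_noise_sd_cm),
            class = "synthetic_config")
}

# analytic taper diameter (cm) at heights h for a synthetic tree
analytic_taper_diameter <- function(h, metrics, taper) {
  H <- metrics$height_m; D <- metrics$dbh_cm
  rel <- pmax(H - h, 0) / (H - 1.3)
  if (taper == "cone") D * rel else D * sqrt(rel)
}

#' Generate one synthetic tree
#'
#' Draws tree dimensions and whorl heights, then runs the structure
#' pipeline generatively (pipe-model basal areas from the analytic
#' taper, branch counts, constrained-uniform branch sizes) and attaches
#' branch dry masses with optional log-normal noise. The stored
#' `pipeline_seed` makes the structure stage exactly reproducible by a
#' re-estimation run over perfect detections.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the tree is a deterministic function of
#'   `(config, seed)`.
#' @param tree_id Identifier for tabular output.
#' @return An object of class `synthetic_tree`: list with `metrics`,
#'   `config`, `pipeline_seed`, `curve` (taper built from noise-free
#'   canonical slices), `whorls`, `branches` (with `dry_mass_g` truth),
#'   `branch_heights_m` (true "0"-branch attachment heights) and
#'   `total_kg`.
#' @export
generate_tree <- function(config = synthetic_config(), seed = 1L,
                          tree_id = sprintf("synth%d", seed)) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    H <- stats::runif(1, config$height_range[1], config$height_range[2])
    D <- stats::runif(1, config$dbh_range[1], config$dbh_range[2])
    cr <- stats::runif(1, config$crown_ratio_range[1],
                       config$crown_ratio_range[2])
    metrics <- tree_metrics(H, D, H * (1 - cr), tree_id = tree_id)

    # whorl heights: treetop downward, truncated-normal annual spacing
    hs <- numeric(0)
    cur <- H
    repeat {
      sp <- stats::rnorm(1, config$whorl_spacing_mean,
                         config$whorl_spacing_sd)
      sp <- min(max(sp, 0.05), 0.5)
      cur <- cur - sp
      if (cur < metrics$crown_base_m) break
      hs <- c(hs, cur)
    }
    if (!length(hs)) {
      warning("crown shorter than one whorl spacing; single-whorl tree")
      hs <- metrics$crown_base_m
    }
    pipeline_seed <- sample.int(.Machine$integer.max, 1)
    noise_seed <- sample.int(.Machine$integer.max, 1)

    series <- new_whorl_series(metrics, hs, rep(FALSE, length(hs)),
                               lapply(hs, function(x) x))
    slices <- generate_slices_internal(metrics, config, noise_sd_cm = 0)
    curve <- build_taper_curve(slices, metrics)
    pred <- run_structure_pipeline(series, curve, config$structure,
                                   rng_seed = pipeline_seed)
    bm <- predict_branch_biomass(pred, config$biomass)
    br <- bm$branches
    if (config$biomass_log_sd > 0 && nrow(br)) {
      z <- with_seed(noise_seed,
                     stats::rnorm(nrow(br), 0, config$biomass_log_sd))
      # unit-mean multiplicative noise on the natural-log scale
      br$dry_mass_g <- br$dry_mass_g *
        exp(z - config$biomass_log_sd^2 / 2)
    }
    br$whorl_height_m <- pred$whorls$whorl_height_m[
      match(br$whorl_index, pred$whorls$whorl_index)]
    branch_heights <- br$whorl_height_m

    structure(list(metrics = metrics, config = config, seed = seed,
                   pipeline_seed = pipeline_seed, curve = curve,
                   whorls = pred$whorls, branches = br,
                   branch_heights_m = branch_heights,
                   total_kg = tree_total_tsm(br$dry_mass_g)),
              class = "synthetic_tree")
  })
}

#' @export
print.synthetic_tree <- function(x, ...) {
  cat(sprintf("Synthetic tree '%s': H %.1f m, DBH %.1f cm, %d whorls, %d branches, %.1f kg branch biomass\n",
              x$metrics$tree_id, x$metrics$height_m, x$metrics$dbh_cm,
              nrow(x$whorls), nrow(x$branches), x$total_kg))
  invisible(x)
}

#' Simulate TLS branch detections for a synthetic tree
#'
#' Each true trunk-attached branch is retained with the logistic
#' probability `plogis(a + b * h_r)` (low retention near the treetop,
#' emulating occlusion) and retained attachment heights receive
#' Gaussian jitter. Output is sorted by height.
#'
#' @param tree A [generate_tree()] result.
#' @param config A [synthetic_config()]; defaults to the tree's own.
#' @param seed Integer seed for the detection draws.
#' @return data.frame with `tree_id` and `branch_height_m`.
#' @export
simulate_detections <- function(tree, config = tree$config, seed = 1L) {
  stopifnot(inherits(tree, "synthetic_tree"))
  h <- tree$branch_heights_m
  if (!length(h))
    return(data.frame(tree_id = character(0), branch_height_m = numeric(0)))
  with_seed(seed, {
    h_r <- pmin(pmax(relative_height(h, tree$metrics), 0), 1)
    p <- stats::plogis(config$retention_intercept +
                         config$retention_slope * h_r)
    keep <- stats::runif(length(h)) < p
    out <- h[keep]
    if (config$height_jitter_sd > 0 && length(out))
      out <- out + stats::rnorm(length(out), 0, config$height_jitter_sd)
    out <- pmin(pmax(out, 0.01), tree$metrics$height_m - 0.01)
    data.frame(tree_id = rep(tree$metrics$tree_id, length(out)),
               branch_height_m = sort(out))
  })
}

generate_slices_internal <- function(metrics, config, noise_sd_cm) {
  cb <- metrics$crown_base_m; HC <- metrics$crown_length_m
  h <- c(0.3, 1.3, cb / 2, cb, cb + c(0.25, 0.5, 0.75, 0.9) * HC)
  h <- sort(unique(round(h, 2)))
  h <- h[h > 0 & h < metrics$height_m]
  d <- analytic_taper_diameter(h, metrics, config$taper)
  if (noise_sd_cm > 0)
    d <- pmax(d + stats::rnorm(length(d), 0, noise_sd_cm), 0)
  data.frame(tree_id = rep(metrics$tree_id, length(h)), height_m = h,
             diameter_cm = d)
}

#' Measured stem slices for a synthetic tree
#'
#' Emulates the eight canonical measurement points (stump, breast
#' height, half crown base, crown base, and 25/50/75/90 % of crown
#' length) on the tree's analytic taper, with optional Gaussian
#' diameter noise.
#'
#' @param tree A [generate_tree()] result.
#' @param noise_sd_cm Gaussian diameter noise sd (cm).
#' @param seed Integer seed (used only when `noise_sd_cm > 0`).
#' @return data.frame with `tree_id`, `height_m`, `diameter_cm`.
#' @export
generate_slices <- function(tree, noise_sd_cm = tree$config$slice_noise_sd_cm,
                            seed = 1L) {
  stopifnot(inherits(tree, "synthetic_tree"))
  if (noise_sd_cm > 0)
    with_seed(seed,
              generate_slices_internal(tree$metrics, tree$config,
                                       noise_sd_cm))
  else generate_slices_internal(tree$metrics, tree$config, 0)
}
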