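# CSV schemas: tree metrics (tree_id, height_m, dbh_cm, crown_base_m),
# slices (tree_id, height_m, diameter_cm), detections
# (tree_id, branch_height_m), reference whorls
# (tree_id, whorl_height_m, stem_diameter_cm, n_branches optional),
# reference branches (tree_id, whorl_height_m, branch_diameter_mm,
# dry_mass_g optional).

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  num <- setdiff(required, "tree_id")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("parse error in ", basename(path), ", column ", cl,
           ", row ", bad[1], ": non-numeric value")
    df[[cl]] <- v
  }
  df
}

#' Read tree metrics from CSV
#'
#' Expects columns `tree_id, height_m, dbh_cm, crown_base_m`. Unit
#' sanity checks (heights below 60 m, DBH below 120 cm) emit warnings.
#'
#' @param path CSV file path.
#' @return Named list of [tree_metrics()] objects, one per row.
#' @export
read_tree_metrics <- function(path) {
  df <- read_checked_csv(path, c("tree_id", "height_m", "dbh_cm",
                                 "crown_base_m"))
  if (any(df$height_m >= 60))
    warning("tree height(s) of 60 m or more: check units")
  if (any(df$dbh_cm >= 120))
    warning("DBH of 120 cm or more: check units")
  out <- lapply(seq_len(nrow(df)), function(i)
    tree_metrics(df$height_m[i], df$dbh_cm[i], df$crown_base_m[i],
                 tree_id = df$tree_id[i]))
  names(out) <- df$tree_id
  out
}

#' Read stem slice measurements from CSV
#'
#' @param path CSV with columns `tree_id, height_m, diameter_cm`.
#' @return data.frame.
#' @export
read_slices <- function(path) {
  read_checked_csv(path, c("tree_id", "height_m", "diameter_cm"))
}

#' Read trunk-attached branch detections from CSV
#'
#' Rows with attachment heights at or above the tree's height are
#' rejected with a warning when metrics are supplied.
#'
#' @param path CSV with columns `tree_id, branch_height_m`.
#' @param metrics Optional named list of [tree_metrics()] used for
#'   validation.
#' @return data.frame.
#' @export
read_detections <- function(path, metrics = NULL) {
  df <- read_checked_csv(path, c("tree_id", "branch_height_m"))
  if (!is.null(metrics)) {
    keep <- rep(TRUE, nrow(df))
    for (id in unique(df$tree_id)) {
      tm <- metrics[[as.character(id)]]
      if (is.null(tm)) next
      bad <- df$tree_id == id & df$branch_height_m >= tm$height_m
      if (any(bad)) {
        warning(sum(bad), " detection(s) at or above tree height for tree '",
                id, "' rejected")
        keep <- keep & !bad
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df
}

#' Run configuration for the estimation pipeline
#'
#' Bundles whorl-rule constants (3-cm cluster threshold, 0.5-m treetop
#' gap, 25-cm fake-whorl interval), the model parameter sets and the
#' seed. All defaults are the method's published constants.
#'
#' @param cluster_threshold_m Whorl clustering gap (m).
#' @param gap_threshold_m Maximum tolerated topmost-whorl-to-treetop
#'   distance (m) before fake whorls are inserted.
#' @param fake_interval_m Fake-whorl spacing (m).
#' @param insert_fake Insert fake whorls at all.
#' @param structure,biomass Model parameter sets.
#' @param seed Integer RNG seed for branch-size sampling.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cluster_threshold_m = 0.03, gap_threshold_m = 0.5,
                       fake_interval_m = 0.25, insert_fake = TRUE,
                       structure = structure_params(),
                       biomass = biomass_params(), seed = 1L) {
  stopifnot(cluster_threshold_m >= 0, gap_threshold_m >= 0,
            fake_interval_m > 0,
            inherits(structure, "structure_params"),
            inherits(biomass, "biomass_params"))
  structure(list(cluster_threshold_m = cluster_threshold_m,
                 gap_threshold_m = gap_threshold_m,
                 fake_interval_m = fake_interval_m,
                 insert_fake = isTRUE(insert_fake),
                 structure = structure, biomass = biomass,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Recognized top-level keys: the [run_config()] scalars plus
#' `structure` (eta, m1, m3max, m3min, eta_in_eq3) and `biomass`
#' (m4, rho_b, phi_b, eta_ratio, allo) override blocks.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- do.call(structure_params, as.list(js$structure))
  bp <- do.call(biomass_params, as.list(js$biomass))
  args <- js[intersect(names(js),
                       c("cluster_threshold_m", "gap_threshold_m",
                         "fake_interval_m", "insert_fake", "seed"))]
  do.call(run_config, c(args, list(structure = sp, biomass = bp)))
}

#' Estimate whorl and branch attributes for one tree
#'
#' End-to-end single-tree run: builds the taper curve from slices,
#' clusters the detections into whorls, inserts fake whorls in the
#' upper crown, applies the structure models and the branch dry-mass
#' model, and computes all four tree-total estimators (summation, and
#' the cylinder-volume, stump-allometry and crown-base-allometry
#' comparisons).
#'
#' @param metrics A [tree_metrics()] object.
#' @param slices Slice data.frame (`height_m`, `diameter_cm`).
#' @param detections Numeric vector (or data.frame with
#'   `branch_height_m`) of trunk-attached branch heights.
#' @param config A [run_config()].
#' @param branch_volume_m3 Optional reconstructed branch cylinder
#'   volume for the volume-based comparison estimator.
#' @return A list of class `tree_estimate`: `metrics`, `curve`,
#'   `series`, `prediction`, `branches` (with dry mass), `profile`,
#'   `totals_kg` (named: tsm_tls, qsm_allometry, qsm_crobas and, when
#'   volume is given, treeqsm_volume), `config`.
#' @export
estimate_tree <- function(metrics, slices, detections,
                          config = run_config(),
                          branch_volume_m3 = NULL) {
  stopifnot(inherits(metrics, "tree_metrics"), inherits(config, "run_config"))
  if (is.data.frame(detections)) detections <- detections$branch_height_m
  curve <- build_taper_curve(slices, metrics)
  series <- cluster_detections(detections, metrics,
                               threshold = config$cluster_threshold_m)
  if (config$insert_fake && length(series))
    series <- insert_fake_whorls(series, config$gap_threshold_m,
                                 config$fake_interval_m)
  pred <- run_structure_pipeline(series, curve, config$structure,
                                 rng_seed = config$seed)
  bm <- predict_branch_biomass(pred, config$biomass)

  totals <- c(tsm_tls = bm$total_kg,
              qsm_allometry = allometry_biomass(2 + 1.25 * metrics$dbh_cm,
                                                metrics$height_m,
                                                config$biomass),
              qsm_crobas = crobas_biomass(
                stem_area_at(curve, metrics$crown_base_m) / 1e4,
                config$biomass))
  if (!is.null(branch_volume_m3))
    totals <- c(totals,
                treeqsm_volume = qsm_volume_biomass(branch_volume_m3,
                                                    config$biomass))
  structure(list(metrics = metrics, curve = curve, series = series,
                 prediction = pred, branches = bm$branches,
                 profile = bm$profile, totals_kg = totals,
                 config = config),
            class = "tree_estimate")
}

#' @export
print.tree_estimate <- function(x, ...) {
  cat(sprintf("Branch estimate for tree '%s': %d whorls (%d inserted), %d branches\n",
              x$metrics$tree_id, nrow(x$prediction$whorls),
              sum(x$prediction$whorls$is_fake), nrow(x$branches)))
  for (nm in names(x$totals_kg))
    cat(sprintf("  %-15s %8.2f kg\n", nm, x$totals_kg[[nm]]))
  invisible(x)
}

#' Run the estimation pipeline over input files
#'
#' Reads the metrics, slice and detection tables, estimates every tree,
#' and (optionally) writes whorl, branch and total tables plus a JSON
#' manifest recording parameters and seed to `out_dir`.
#'
#' @param metrics_path,slices_path,detections_path Input CSV paths.
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Named list of `tree_estimate` objects, invisibly when
#'   writing.
#' @export
run_pipeline <- function(metrics_path, slices_path, detections_path,
                         config = run_config(), out_dir = NULL) {
  metrics <- read_tree_metrics(metrics_path)
  slices <- read_slices(slices_path)
  detections <- read_detections(detections_path, metrics)
  est <- lapply(metrics, function(tm) {
    id <- tm$tree_id
    estimate_tree(tm, slices[slices$tree_id == id, , drop = FALSE],
                  detections$branch_height_m[detections$tree_id == id],
                  config)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    whorls <- do.call(rbind, lapply(est, function(e)
      cbind(tree_id = e$metrics$tree_id, e$prediction$whorls)))
    branches <- do.call(rbind, lapply(est, function(e)
      if (nrow(e$branches))
        cbind(tree_id = e$metrics$tree_id,
              e$branches[c("whorl_index", "branch_rank", "basal_area_cm2",
                           "diameter_mm", "dry_mass_g")])))
    totals <- do.call(rbind, lapply(est, function(e)
      data.frame(tree_id = e$metrics$tree_id,
                 method = names(e$totals_kg),
                 total_branch_biomass_kg = unname(e$totals_kg))))
    utils::write.csv(whorls, file.path(out_dir, "whorls.csv"),
                     row.names = FALSE)
    utils::write.csv(branches, file.path(out_dir, "branches.csv"),
                     row.names = FALSE)
    utils::write.csv(totals, file.path(out_dir, "totals.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "whorltls",
      version = as.character(utils::packageVersion("whorltls")),
      seed = config$seed,
      cluster_threshold_m = config$cluster_threshold_m,
      gap_threshold_m = config$gap_threshold_m,
      fake_interval_m = config$fake_interval_m,
      insert_fake = config$insert_fake,
      eta = config$structure$eta,
      eta_in_eq3 = config$structure$eta_in_eq3,
      m1 = config$structure$m1, m3max = config$structure$m3max,
      m3min = config$structure$m3min, m4 = config$biomass$m4,
      rho_b = config$biomass$rho_b, phi_b = config$biomass$phi_b,
      eta_ratio = config$biomass$eta_ratio, allo = config$biomass$allo,
      inputs = c(metrics_path, slices_path, detections_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(est))
  }
  est
}
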