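#' Branch biomass model parameters
#'
#' Coefficients of the log-linear individual-branch dry-mass model
#' (fixed part only) plus the constants of the three TLS-based
#' comparison estimators: cylinder-volume times wood density, the
#' stump-diameter/height allometry, and the crown-base pipe-model
#' allometry.
#'
#' @param m4 Branch dry-mass coefficients `c(b0, b1)` in
#'   `ln w = b0 + b1 * (ln d)^0.22` with `d` in mm and `w` in g.
#' @param rho_b Branch wood density (kg m^-3).
#' @param phi_b Crown-base allometry shape constant.
#' @param eta_ratio Ratio of stem to branch pipe-model coefficients.
#' @param allo Stump-diameter allometry coefficients `c(a, b, c)` in
#'   `ln W_b = a + b * dS/(dS + 6) + c * H/(H + 1)` (dS in cm, H in m,
#'   W_b in kg).
#' @return An object of class `biomass_params`.
#' @examples
#' biomass_params()
#' @export
biomass_params <- function(m4 = c(-36.100, 32.514), rho_b = 400,
                           phi_b = 1.16, eta_ratio = 1.65,
                           allo = c(-6.16, 15.08, -2.62)) {
  stopifnot(length(m4) == 2L, rho_b > 0, phi_b > 0, eta_ratio > 0,
            length(allo) == 3L)
  structure(list(m4 = as.numeric(m4), rho_b = rho_b, phi_b = phi_b,
                 eta_ratio = eta_ratio, allo = as.numeric(allo)),
            class = "biomass_params")
}

#' @export
print.biomass_params <- function(x, ...) {
  cat("Branch biomass parameters\n")
  cat(sprintf("  ln w = %.3f + %.3f (ln d)^0.22  [d mm, w g]\n",
              x$m4[1], x$m4[2]))
  cat(sprintf("  rho_b = %g kg/m^3, phi_b = %g, eta_s/eta_b = %g\n",
              x$rho_b, x$phi_b, x$eta_ratio))
  cat(sprintf("  allometry a, b, c = %g, %g, %g\n",
              x$allo[1], x$allo[2], x$allo[3]))
  invisible(x)
}

#' Individual branch dry biomass from diameter
#'
#' Fixed part of the log-linear branch dry-mass model,
#' `w = exp(b0 + b1 * (ln d)^0.22)` with diameter in mm and mass in
#' grams. Diameters of 1 mm or less are outside the model support and
#' are assigned zero mass with a warning.
#'
#' @param diameter_mm Branch diameter(s) in mm.
#' @param params A [biomass_params()] object.
#' @return Dry mass(es) in g.
#' @examples
#' branch_biomass(30)  # ~ 640 g
#' @export
branch_biomass <- function(diameter_mm, params = biomass_params()) {
  stopifnot(inherits(params, "biomass_params"))
  d <- as.numeric(diameter_mm)
  out <- numeric(length(d))
  ok <- d > 1
  if (any(!ok))
    warning(sum(!ok), " branch(es) with diameter <= 1 mm set to zero mass (below model support)")
  b <- params$m4
  out[ok] <- exp(b[1] + b[2] * log(d[ok])^0.22)
  out
}

#' Tree total branch biomass by summation
#'
#' @param dry_mass_g Individual branch dry masses in g (possibly empty).
#' @return Total branch biomass in kg.
#' @examples
#' tree_total_tsm(c(500, 1500))  # 2 kg
#' @export
tree_total_tsm <- function(dry_mass_g) {
  sum(as.numeric(dry_mass_g)) / 1000
}

#' Branch biomass from reconstructed cylinder volume
#'
#' Comparison estimator: total branch cylinder volume from a quantitative
#' structure model multiplied by branch wood density.
#'
#' @param branch_volume_m3 Total branch volume (m^3, >= 0).
#' @param params A [biomass_params()] object.
#' @return Branch biomass in kg.
#' @examples
#' qsm_volume_biomass(0.05)  # 20 kg
#' @export
qsm_volume_biomass <- function(branch_volume_m3, params = biomass_params()) {
  stopifnot(inherits(params, "biomass_params"))
  if (any(branch_volume_m3 < 0)) stop("branch volume must be non-negative")
  branch_volume_m3 * params$rho_b
}

#' Branch biomass from stump-diameter allometry
#'
#' Comparison estimator: `W_b = exp(a + b * dS/(dS+6) + c * H/(H+1))`
#' with the stump diameter in cm and height in m.
#'
#' @param stump_diameter_cm Stump diameter (cm, > 0). A common surrogate
#'   when unmeasured is `2 + 1.25 * DBH`.
#' @param height_m Tree height (m, > 0).
#' @param params A [biomass_params()] object.
#' @return Branch biomass in kg.
#' @examples
#' allometry_biomass(2 + 1.25 * 30, 25)
#' @export
allometry_biomass <- function(stump_diameter_cm, height_m,
                              params = biomass_params()) {
  stopifnot(inherits(params, "biomass_params"))
  if (any(stump_diameter_cm <= 0) || any(height_m <= 0))
    stop("stump diameter and height must be positive")
  a <- params$allo
  exp(a[1] + a[2] * stump_diameter_cm / (stump_diameter_cm + 6) +
        a[3] * height_m / (height_m + 1))
}

#' Branch biomass from the crown-base pipe-model allometry
#'
#' Comparison estimator: `W_b = rho_b * phi_b * (eta_s/eta_b) * A_c`
#' with the stem cross-sectional area at the crown base in m^2.
#'
#' @param crown_base_area_m2 Stem area at crown base (m^2, >= 0).
#' @param params A [biomass_params()] object.
#' @return Branch biomass in kg.
#' @examples
#' crobas_biomass(0.05)  # 400 * 1.16 * 1.65 * 0.05 = 38.28 kg
#' @export
crobas_biomass <- function(crown_base_area_m2, params = biomass_params()) {
  stopifnot(inherits(params, "biomass_params"))
  if (any(crown_base_area_m2 < 0)) stop("crown base area must be non-negative")
  params$rho_b * params$phi_b * params$eta_ratio * crown_base_area_m2
}

#' Refit the fixed part of the branch dry-mass model
#'
#' Ordinary least squares of `ln w` on `(ln d)^0.22` with intercept.
#' Supports parameter-recovery checks of the dry-mass model on data
#' where branch masses are known.
#'
#' @param diameters_mm Branch diameters (mm), all > 1.
#' @param masses_g Branch dry masses (g), all > 0.
#' @return A list with `b0`, `b1`, their standard errors `se0`, `se1`,
#'   and the underlying `lm` fit.
#' @examples
#' d <- c(5, 10, 20, 40)
#' w <- exp(-36.1 + 32.514 * log(d)^0.22)
#' fit_branch_biomass_fixed(d, w)
#' @export
fit_branch_biomass_fixed <- function(diameters_mm, masses_g) {
  d <- as.numeric(diameters_mm); w <- as.numeric(masses_g)
  if (length(d) != length(w)) stop("diameter and mass vectors differ in length")
  if (length(d) < 3L) stop("at least 3 branches are required")
  if (any(d <= 1)) stop("all diameters must exceed 1 mm")
  if (any(w <= 0)) stop("all masses must be positive")
  x <- log(d)^0.22
  if (max(x) - min(x) < 1e-12) stop("singular design: all diameters equal")
  fit <- stats::lm(log(w) ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(b0 = unname(cf[1]), b1 = unname(cf[2]),
       se0 = unname(se[1]), se1 = unname(se[2]), fit = fit)
}

#' Attach dry mass to predicted branches and summarize by tree
#'
#' Applies the branch dry-mass model to a structure-pipeline result and
#' builds the cumulative vertical biomass profile.
#'
#' @param prediction A `whorl_prediction` from [run_structure_pipeline()].
#' @param params A [biomass_params()] object.
#' @return A list with `branches` (the branch table plus `dry_mass_g`),
#'   `total_kg`, and `profile` (data.frame `h_r`, `cumulative_kg`,
#'   accumulated from treetop downward).
#' @export
predict_branch_biomass <- function(prediction, params = biomass_params()) {
  stopifnot(inherits(prediction, "whorl_prediction"),
            inherits(params, "biomass_params"))
  br <- prediction$branches
  if (nrow(br) == 0L) {
    return(list(branches = cbind(br, dry_mass_g = numeric(0)),
                total_kg = 0,
                profile = data.frame(h_r = numeric(0),
                                     cumulative_kg = numeric(0))))
  }
  br$dry_mass_g <- branch_biomass(br$diameter_mm, params)
  wh <- prediction$whorls
  br$h_r <- wh$h_r[match(br$whorl_index, wh$whorl_index)]
  mass_by_whorl <- tapply(br$dry_mass_g, br$whorl_index, sum)
  idx <- as.integer(names(mass_by_whorl))
  ord <- order(idx)  # whorl_index increases top-down
  profile <- data.frame(
    h_r = wh$h_r[match(idx[ord], wh$whorl_index)],
    cumulative_kg = cumsum(as.numeric(mass_by_whorl[ord])) / 1000)
  list(branches = br, total_kg = tree_total_tsm(br$dry_mass_g),
       profile = profile)
}
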