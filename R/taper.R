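#' Build a stem taper curve from slice diameters
#'
#' Constructs a spline-based stem taper curve from refined slice diameters
#' together with the two known anchor dimensions: the DBH at breast height
#' (1.3 m) and a diameter of zero at the treetop. The curve serves
#' diameter and cross-sectional-area queries at arbitrary heights.
#'
#' The interpolant is an exact cubic spline fitted on the squared-diameter
#' scale (proportional to cross-sectional area), which keeps conic and
#' paraboloid stems exactly representable. The fitted curve is sampled on
#' a 1-cm height grid above breast height and made non-increasing with a
#' pool-adjacent-violators (isotonic) correction, after which the two
#' anchors are re-pinned exactly. Below breast height the diameter is held
#' constant at DBH unless butt slices (below 1.3 m) are supplied, in which
#' case they are joined by linear interpolation.
#'
#' @param slices A data.frame with columns `height_m` and `diameter_cm`
#'   (refined stem slice diameters). At least 3 slices are required;
#'   heights must be unique and in (0, H).
#' @param metrics A [tree_metrics()] object.
#' @param grid_step_m Sampling step of the monotonicity grid (m).
#'
#' @return An object of class `taper_curve`.
#' @examples
#' tm <- tree_metrics(25, 30, 15)
#' h <- c(0.3, 2, 5, 8, 11, 14, 18, 22)
#' sl <- data.frame(height_m = h, diameter_cm = 30 * (25 - h) / (25 - 1.3))
#' tc <- build_taper_curve(sl, tm)
#' stem_diameter_at(tc, 1.3)   # 30
#' stem_diameter_at(tc, 25)    # 0
#' @export
build_taper_curve <- function(slices, metrics, grid_step_m = 0.01) {
  stopifnot(inherits(metrics, "tree_metrics"), is.data.frame(slices))
  need <- c("height_m", "diameter_cm")
  miss <- setdiff(need, names(slices))
  if (length(miss))
    stop("slices is missing column(s): ", paste(miss, collapse = ", "))
  h <- as.numeric(slices$height_m)
  d <- as.numeric(slices$diameter_cm)
  if (anyNA(h) || anyNA(d)) stop("slices contain missing values")
  if (length(h) < 3L) stop("degenerate input: at least 3 stem slices are required")
  if (anyDuplicated(h)) stop("slice heights must be unique")
  H <- metrics$height_m
  if (any(h <= 0 | h >= H)) stop("slice heights must lie strictly within (0, H)")
  if (any(d < 0)) stop("slice diameters must be non-negative")

  ord <- order(h)
  h <- h[ord]; d <- d[ord]

  # flag suspect slices: diameter growing by >20 % upwards above breast height
  above <- h >= 1.3
  if (sum(above) >= 2L) {
    da <- d[above]
    growth <- da[-1] / pmax(da[-length(da)], .Machine$double.eps)
    if (any(growth > 1.2))
      warning("suspect slice: diameter increases by >20% between consecutive heights above breast height")
  }

  # knots: slices plus anchors (1.3, DBH) and (H, 0); anchors win on collision
  keep <- abs(h - 1.3) > 1e-9
  hk <- c(h[keep], 1.3, H)
  dk <- c(d[keep], metrics$dbh_cm, 0)
  ord <- order(hk)
  hk <- hk[ord]; dk <- dk[ord]

  sq <- stats::splinefun(hk, dk^2, method = "fmm")

  grid <- seq(1.3, H, by = grid_step_m)
  if (grid[length(grid)] < H) grid <- c(grid, H)
  v <- pmax(sq(grid), 0)

  # isotonic (pool-adjacent-violators) enforcement of non-increase
  iso <- stats::isoreg(grid, -v)
  v <- -iso$yf
  v[1] <- metrics$dbh_cm^2
  v <- pmin(v, v[1])
  v <- pmax(v, 0)
  v[length(v)] <- 0

  # butt profile below breast height
  butt <- NULL
  if (any(h < 1.3)) {
    hb <- c(h[h < 1.3], 1.3)
    db <- c(d[h < 1.3], metrics$dbh_cm)
    butt <- list(height_m = hb, diameter_cm = db)
  }

  structure(
    list(tree = metrics,
         knots = data.frame(height_m = hk, diameter_cm = dk),
         grid_h = grid, grid_d2 = v, butt = butt),
    class = "taper_curve")
}

#' @export
print.taper_curve <- function(x, ...) {
  cat(sprintf("Stem taper curve for tree '%s': %d knots, DBH %.1f cm, H %.2f m\n",
              x$tree$tree_id, nrow(x$knots), x$tree$dbh_cm, x$tree$height_m))
  invisible(x)
}

#' Stem diameter at a given height
#'
#' @param curve A [build_taper_curve()] result.
#' @param h Height(s) in m; must lie in `[0, H]`.
#' @return Diameter(s) in cm.
#' @examples
#' tm <- tree_metrics(25, 30, 15)
#' sl <- data.frame(height_m = c(2, 8, 16), diameter_cm = c(29.1, 21.5, 11.4))
#' stem_diameter_at(build_taper_curve(sl, tm), c(1.3, 25))
#' @export
stem_diameter_at <- function(curve, h) {
  stopifnot(inherits(curve, "taper_curve"), is.numeric(h))
  H <- curve$tree$height_m
  if (any(h < -1e-9 | h > H + 1e-9))
    stop("height query outside [0, H]")
  h <- pmin(pmax(h, 0), H)
  out <- numeric(length(h))
  up <- h >= 1.3
  if (any(up)) {
    d2 <- stats::approx(curve$grid_h, curve$grid_d2, xout = h[up],
                        rule = 2)$y
    out[up] <- sqrt(pmax(d2, 0))
  }
  if (any(!up)) {
    if (is.null(curve$butt)) {
      out[!up] <- curve$tree$dbh_cm
    } else {
      out[!up] <- stats::approx(curve$butt$height_m, curve$butt$diameter_cm,
                                xout = h[!up], rule = 2)$y
    }
  }
  out
}

#' Stem cross-sectional area at a given height
#'
#' Area is computed from the taper diameter as `pi * d^2 / 4`.
#'
#' @inheritParams stem_diameter_at
#' @return Cross-sectional area(s) in cm^2.
#' @examples
#' tm <- tree_metrics(25, 30, 15)
#' sl <- data.frame(height_m = c(2, 8, 16), diameter_cm = c(29.1, 21.5, 11.4))
#' stem_area_at(build_taper_curve(sl, tm), 1.3)  # pi * 30^2 / 4
#' @export
stem_area_at <- function(curve, h) {
  d <- stem_diameter_at(curve, h)
  pi * d^2 / 4
}
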