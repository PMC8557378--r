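#' Cluster trunk-attached branch detections into whorls
#'
#' Groups the attachment heights of detected trunk-attached ("0") branches
#' into whorls with a single-linkage chaining rule: after sorting by
#' height, two consecutive detections belong to the same whorl whenever
#' their height gap is at most `threshold` (3 cm by default, the empirical
#' within-whorl spread of Scots pine). Whorl height is the arithmetic mean
#' of its member heights. Whorls are indexed 1 from the treetop downward.
#'
#' When the tree's crown base is known, detections below it (dead
#' branches) are excluded before clustering unless
#' `restrict_to_crown = FALSE`.
#'
#' @param heights Numeric vector of detection heights (m).
#' @param tree A [tree_metrics()] object.
#' @param threshold Maximum gap (m) between consecutive detections that
#'   still chains them into one whorl. Inclusive comparison.
#' @param restrict_to_crown Drop detections below the crown base first.
#'
#' @return A `whorl_series` object: list with `tree`, and parallel
#'   vectors/lists `height_m` (decreasing), `is_fake`, `members`
#'   (detection heights per whorl).
#' @examples
#' tm <- tree_metrics(25, 30, 15)
#' ws <- cluster_detections(c(20.0, 20.02, 20.2), tm)
#' whorl_table(ws)
#' @export
cluster_detections <- function(heights, tree, threshold = 0.03,
                               restrict_to_crown = TRUE) {
  stopifnot(inherits(tree, "tree_metrics"), is.numeric(threshold),
            threshold >= 0)
  heights <- as.numeric(heights)
  if (anyNA(heights) || any(!is.finite(heights)))
    stop("detection heights must be finite")
  if (restrict_to_crown)
    heights <- heights[heights >= tree$crown_base_m]
  if (length(heights) == 0L) {
    warning("no detections to cluster; returning an empty whorl series")
    return(new_whorl_series(tree, numeric(0), logical(0), list()))
  }
  hs <- sort(heights)  # stable: ties keep input order
  gap <- diff(hs)
  # new cluster starts where the gap to the previous detection exceeds the
  # threshold (inclusive rule: gap == threshold chains)
  cl <- cumsum(c(1, as.integer(gap > threshold + 1e-12)))
  members <- split(hs, cl)
  hm <- vapply(members, mean, numeric(1))
  ord <- order(hm, decreasing = TRUE)
  new_whorl_series(tree, unname(hm[ord]), rep(FALSE, length(ord)),
                   unname(members[ord]))
}

new_whorl_series <- function(tree, height_m, is_fake, members) {
  structure(list(tree = tree, height_m = height_m, is_fake = is_fake,
                 members = members),
            class = "whorl_series")
}

#' @export
print.whorl_series <- function(x, ...) {
  cat(sprintf("Whorl series for tree '%s': %d whorls (%d inserted)\n",
              x$tree$tree_id, length(x$height_m), sum(x$is_fake)))
  invisible(x)
}

#' @export
length.whorl_series <- function(x) length(x$height_m)

#' Tabulate a whorl series
#'
#' @param series A `whorl_series`.
#' @return data.frame with `tree_id`, `whorl_index` (1 = topmost),
#'   `whorl_height_m`, `is_fake`, `n_detected`.
#' @export
whorl_table <- function(series) {
  stopifnot(inherits(series, "whorl_series"))
  data.frame(
    tree_id = rep(series$tree$tree_id, length(series$height_m)),
    whorl_index = seq_along(series$height_m),
    whorl_height_m = series$height_m,
    is_fake = series$is_fake,
    n_detected = vapply(series$members, length, integer(1)))
}

#' Insert fake whorls in the under-detected upper crown
#'
#' TLS detects few or no branches near the treetop. Whenever the distance
#' from the topmost whorl to the treetop exceeds `gap_threshold` (0.5 m),
#' fake whorls are inserted stepping upward from the current topmost whorl
#' at a fixed `interval` (25 cm) until the remaining gap is at most
#' `gap_threshold`. Fake whorls carry no member detections and are
#' flagged. The operation is idempotent.
#'
#' @param series A `whorl_series` with at least one whorl.
#' @param gap_threshold Maximum tolerated distance (m) from topmost whorl
#'   to treetop.
#' @param interval Spacing (m) of inserted whorls.
#' @return A re-indexed `whorl_series`.
#' @examples
#' tm <- tree_metrics(25, 30, 15)
#' ws <- cluster_detections(23.8, tm)
#' whorl_table(insert_fake_whorls(ws))  # fills 23.8 m .. treetop
#' @export
insert_fake_whorls <- function(series, gap_threshold = 0.5, interval = 0.25) {
  stopifnot(inherits(series, "whorl_series"))
  if (interval <= 0) stop("interval must be positive")
  if (gap_threshold < 0) stop("gap_threshold must be non-negative")
  if (length(series$height_m) == 0L) return(series)
  H <- series$tree$height_m
  top <- series$height_m[1]
  add <- numeric(0)
  while (H - top > gap_threshold + 1e-12) {
    top <- top + interval
    add <- c(add, top)
  }
  if (!length(add)) return(series)
  hm <- c(series$height_m, add)
  fk <- c(series$is_fake, rep(TRUE, length(add)))
  mb <- c(series$members, rep(list(numeric(0)), length(add)))
  ord <- order(hm, decreasing = TRUE)
  new_whorl_series(series$tree, hm[ord], fk[ord], mb[ord])
}

#' Relative height within the crown
#'
#' Distance from the treetop divided by crown length: 0 at the treetop,
#' 1 at the crown base.
#'
#' @param height_m Whorl height(s) (m), at most tree height.
#' @param tree A [tree_metrics()] object.
#' @return Dimensionless relative height(s).
#' @examples
#' relative_height(20, tree_metrics(25, 30, 15))  # 0.5
#' @export
relative_height <- function(height_m, tree) {
  stopifnot(inherits(tree, "tree_metrics"))
  if (tree$crown_length_m <= 0) stop("crown length must be positive")
  if (any(height_m > tree$height_m + 1e-9))
    stop("whorl height exceeds tree height")
  (tree$height_m - height_m) / tree$crown_length_m
}
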