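#' Per-tree summary metrics
#'
#' Container for the scalar dimensions of a single tree: total height,
#' diameter at breast height (1.3 m), and crown base. Crown length is
#' derived as `height_m - crown_base_m`.
#'
#' @param height_m Total tree height H (m).
#' @param dbh_cm Diameter at breast height (cm).
#' @param crown_base_m Height of the lowest living branch (m).
#' @param tree_id Identifier used in tabular output.
#'
#' @return An object of class `tree_metrics` with fields `height_m`,
#'   `dbh_cm`, `crown_base_m`, `crown_length_m`, `tree_id`.
#' @examples
#' tree_metrics(25, 30, 15)
#' @export
tree_metrics <- function(height_m, dbh_cm, crown_base_m, tree_id = "tree") {
  stopifnot(is.numeric(height_m), length(height_m) == 1L, is.finite(height_m),
            is.numeric(dbh_cm), length(dbh_cm) == 1L, is.finite(dbh_cm),
            is.numeric(crown_base_m), length(crown_base_m) == 1L,
            is.finite(crown_base_m))
  if (height_m <= 0) stop("tree height must be positive")
  if (dbh_cm <= 0) stop("dbh_cm must be positive")
  if (crown_base_m <= 0 || crown_base_m >= height_m)
    stop("crown_base_m must lie strictly between 0 and tree height")
  structure(
    list(height_m = height_m, dbh_cm = dbh_cm, crown_base_m = crown_base_m,
         crown_length_m = height_m - crown_base_m,
         tree_id = as.character(tree_id)),
    class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf("Tree '%s': H = %.2f m, DBH = %.1f cm, crown base = %.2f m (crown length %.2f m)\n",
              x$tree_id, x$height_m, x$dbh_cm, x$crown_base_m, x$crown_length_m))
  invisible(x)
}
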