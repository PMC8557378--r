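#' Published six-tree whorl/branch detection counts
#'
#' Paired (`n_p`), commission (`n_c`) and omission (`n_o`) counts from
#' an evaluation of whorl and branch detection on six destructively
#' measured old Scots pines, per tree, crown layer and detection method
#' (direct cylinder-model extraction, `treeqsm`, vs the structure-model
#' pipeline, `tsm_tls`), together with the percentages as published.
#' The percentage columns serve as worked-example expectations for
#' [detection_metrics()]; for a handful of rows the published
#' percentages are not internally consistent with the counts (they do
#' not sum to 100), so the counts are authoritative.
#'
#' @return data.frame with columns `level` (whorl/branch), `tree`
#'   (tree id or `all`), `layer` (total/upper/middle/lower), `method`,
#'   `n_ref`, `n_total`, `n_p`, `n_c`, `n_o`, `accuracy_pct`, `ec_pct`,
#'   `eo_pct`.
#' @examples
#' counts <- detection_count_table()
#' subset(counts, tree == "all" & method == "tsm_tls")
#' @export
detection_count_table <- function() {
  path <- system.file("extdata", "detection_counts.csv",
                      package = "whorltls", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(tree = "character"))
}
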