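#' Score a candidate cluster by single-copy markers
#'
#' Completeness is the percentage of the expected marker set observed at
#' least once in the cluster; purity is the percentage of observed markers
#' occurring exactly once. A cluster with no markers at all is vacuously
#' 100% pure (and 0% complete).
#'
#' @param contigs Character vector of contig ids in the cluster.
#' @param marker_hits Data frame `contig`, `marker_id`, one row per marker
#'   occurrence; ids outside `marker_set` are dropped with a warning.
#' @param marker_set Character vector of expected single-copy marker ids.
#' @return List with `completeness`, `purity` (both percentages) and
#'   `marker_counts`, a named integer vector of per-marker copy numbers.
#' @export
score_cluster <- function(contigs, marker_hits, marker_set) {
  if (length(marker_set) == 0L) stop("marker set is empty")
  marker_set <- unique(marker_set)
  stopifnot(length(contigs) > 0L)
  hits <- marker_hits[marker_hits$contig %in% contigs, , drop = FALSE]
  foreign <- !(hits$marker_id %in% marker_set)
  if (any(foreign)) {
    warning(sum(foreign), " marker hit(s) outside the marker set dropped")
    hits <- hits[!foreign, , drop = FALSE]
  }
  counts <- table(factor(hits$marker_id, levels = marker_set))
  present <- counts[counts > 0]
  completeness <- 100 * length(present) / length(marker_set)
  purity <- if (length(present) == 0L) 100 else
    100 * sum(present == 1) / length(present)
  list(completeness = completeness, purity = purity,
       marker_counts = stats::setNames(as.integer(present), names(present)))
}

#' Does a cluster pass the completeness/purity gate?
#'
#' Strict inequalities: a cluster must be strictly above both thresholds.
#'
#' @param score Output of [score_cluster()] (or any list with
#'   `completeness` and `purity`).
#' @param completeness_min,purity_min Gate thresholds in percent
#'   (defaults 20 and 90).
#' @export
passes_gate <- function(score, completeness_min = 20, purity_min = 90) {
  score$completeness > completeness_min && score$purity > purity_min
}

#' Read marker hits from a TSV
#'
#' @param path Headered TSV with columns `contig`, `marker_id`.
#' @return Tibble, one row per marker occurrence.
#' @export
read_marker_hits <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
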