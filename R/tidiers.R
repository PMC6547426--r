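#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-bin summary of a binning result
#'
#' @param x A `bin_result` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble, one row per bin: contig count, total length, marker
#'   completeness/purity, recruited-contig count and provenance.
#' @method tidy bin_result
#' @export
tidy.bin_result <- function(x, ...) {
  if (nrow(x$assignment) == 0L) {
    return(tibble::tibble(bin = character(), kingdom = character(),
                          n_contigs = integer(), length = numeric(),
                          completeness = numeric(), purity = numeric(),
                          n_recruited = integer()))
  }
  x$assignment |>
    dplyr::left_join(x$contig_taxonomy[, c("contig", "length")],
                     by = "contig") |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      kingdom = dplyr::first(.data$kingdom),
      n_contigs = dplyr::n(),
      length = sum(.data$length),
      completeness = dplyr::first(.data$completeness),
      purity = dplyr::first(.data$purity),
      n_recruited = sum(.data$recruited),
      .groups = "drop"
    )
}

#' One-row summary of a binning result
#'
#' @inheritParams tidy.bin_result
#' @return Tibble with bin, contig and length totals and median bin
#'   statistics.
#' @method glance bin_result
#' @export
glance.bin_result <- function(x, ...) {
  bins <- tidy(x)
  total_len <- sum(x$contig_taxonomy$length)
  tibble::tibble(
    n_bins = nrow(bins),
    n_contigs_binned = nrow(x$assignment),
    n_recruited = sum(x$assignment$recruited %||% FALSE),
    n_unclustered = length(x$unclustered),
    binned_fraction = if (total_len > 0) sum(bins$length) / total_len else NA_real_,
    median_completeness = stats::median(bins$completeness),
    median_purity = stats::median(bins$purity),
    seed = x$seed
  )
}

#' Per-genome table of a binning evaluation
#' @param x A `bin_evaluation` from [evaluate_binning()].
#' @param ... Unused.
#' @method tidy bin_evaluation
#' @export
tidy.bin_evaluation <- function(x, ...) x$per_genome

#' One-row summary of a binning evaluation
#' @inheritParams tidy.bin_evaluation
#' @method glance bin_evaluation
#' @export
glance.bin_evaluation <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall, f1 = x$f1,
                 median_f1 = x$median_f1, f1_recovery = x$f1_recovery,
                 n_genomes = nrow(x$per_genome), unbinned_bp = x$unbinned,
                 excluded_bp = x$excluded)
}
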