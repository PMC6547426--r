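#' Plot the t-SNE embedding coloured by bin
#'
#' Binned contigs are coloured by bin; unclustered contigs are grey
#' crosses. Point size scales with coverage.
#'
#' @param object A `bin_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bin_result
#' @export
autoplot.bin_result <- function(object, ...) {
  emb <- dplyr::left_join(object$embedding,
                          object$assignment[, c("contig", "bin")],
                          by = "contig")
  emb <- dplyr::left_join(emb,
                          object$contig_taxonomy[, c("contig", "coverage")],
                          by = "contig")
  ggplot2::ggplot(emb, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      data = function(d) d[is.na(d$bin), ],
      shape = 4, colour = "grey60", alpha = 0.6,
      ggplot2::aes(size = .data$coverage)
    ) +
    ggplot2::geom_point(
      data = function(d) d[!is.na(d$bin), ],
      alpha = 0.7,
      ggplot2::aes(colour = .data$bin, size = .data$coverage)
    ) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "bin") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot recruitment confidence against outcome
#'
#' Bar chart of accepted/rejected predictions per jackknife confidence
#' level — the diagnostic view of how confidence tracks recruitment.
#'
#' @param log Recruitment log tibble (`confidence`, `accepted`), e.g.
#'   `bin_result$recruitment_log`.
#' @return A ggplot.
#' @export
plot_recruitment <- function(log) {
  ggplot2::ggplot(log, ggplot2::aes(x = factor(.data$confidence),
                                    fill = .data$accepted)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "jackknife confidence (%)", y = "predictions",
                  fill = "accepted") +
    ggplot2::theme_minimal()
}
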