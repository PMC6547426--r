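#' Length-weighted assignment matrix of bins against reference genomes
#'
#' Builds S, where `S[i, j]` is the combined length (bp) of the contigs in
#' bin i that belong to reference genome j, plus the total length of
#' ground-truth contigs left in no bin. Contigs flagged misassembled are
#' excluded from both before scoring (their total is reported separately).
#'
#' @param assignment Data frame `bin`, `contig`.
#' @param truth Data frame `contig`, `genome`, `length`, and optionally
#'   `misassembled` (0/1 or logical).
#' @return List with `S` (matrix bins x genomes), `unbinned` (bp),
#'   `excluded` (bp of misassembled contigs).
#' @export
assignment_matrix <- function(assignment, truth) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("contig", "genome", "length") %in% names(truth)))
  if (!"misassembled" %in% names(truth)) truth$misassembled <- FALSE
  excluded <- sum(truth$length[as.logical(truth$misassembled)])
  truth <- truth[!as.logical(truth$misassembled), , drop = FALSE]
  joined <- dplyr::left_join(truth,
                             tibble::as_tibble(assignment)[, c("bin", "contig")],
                             by = "contig")
  binned <- joined[!is.na(joined$bin), , drop = FALSE]
  genomes <- sort(unique(truth$genome))
  bins <- sort(unique(binned$bin))
  S <- matrix(0, nrow = length(bins), ncol = length(genomes),
              dimnames = list(bins, genomes))
  if (nrow(binned) > 0L) {
    agg <- binned |>
      dplyr::group_by(.data$bin, .data$genome) |>
      dplyr::summarise(len = sum(.data$length), .groups = "drop")
    S[cbind(agg$bin, agg$genome)] <- agg$len
  }
  list(S = S, unbinned = sum(joined$length[is.na(joined$bin)]),
       excluded = excluded)
}

#' Binning precision (percent)
#'
#' The length fraction of each bin taken up by its plurality genome,
#' aggregated over bins: 100 * sum_i max_j S_ij / sum_ij S_ij.
#'
#' @param S Assignment matrix (bins x genomes), lengths in bp.
#' @export
binning_precision <- function(S) {
  tot <- sum(S)
  if (tot <= 0) stop("precision undefined: no binned length")
  100 * sum(apply(S, 1, max)) / tot
}

#' Binning recall (percent)
#'
#' The length fraction of each genome captured by its best bin, aggregated
#' over genomes with unbinned length in the denominator:
#' 100 * sum_j max_i S_ij / (sum_ij S_ij + unbinned).
#'
#' @param S Assignment matrix (bins x genomes).
#' @param unbinned Total length (bp) of genome contigs in no bin.
#' @export
binning_recall <- function(S, unbinned = 0) {
  denom <- sum(S) + unbinned
  if (denom <= 0) stop("recall undefined: zero total length")
  if (nrow(S) == 0L) return(0)
  100 * sum(apply(S, 2, max)) / denom
}

#' F1 score: harmonic mean of precision and recall
#'
#' @param precision,recall Percentages.
#' @return The harmonic mean (0 when both are 0).
#' @export
binning_f1 <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Per-genome F1 scores
#'
#' Each genome is matched to the bin holding its largest length fraction;
#' that bin's purity with respect to the genome gives precision, and the
#' genome fraction captured (out of its total assembled, non-misassembled
#' length) gives recall. Genomes with no binned contigs score 0.
#'
#' @inheritParams binning_recall
#' @param genome_lengths Named vector of total (non-misassembled) bp per
#'   genome; defaults to column sums of S plus nothing, i.e. assumes all
#'   contigs binned. Supply `colSums(S) + per-genome unbinned` for the
#'   general case.
#' @return Tibble `genome`, `bin`, `precision`, `recall`, `f1`.
#' @export
per_genome_f1 <- function(S, genome_lengths = colSums(S)) {
  genomes <- colnames(S)
  purrr::map_dfr(genomes, function(g) {
    tot <- unname(genome_lengths[g])
    if (nrow(S) == 0L || max(S[, g]) == 0 || tot == 0) {
      return(tibble::tibble(genome = g, bin = NA_character_, precision = 0,
                            recall = 0, f1 = 0))
    }
    i <- which.max(S[, g])
    p <- 100 * S[i, g] / sum(S[i, ])
    r <- 100 * S[i, g] / tot
    tibble::tibble(genome = g, bin = rownames(S)[i], precision = p,
                   recall = r, f1 = binning_f1(p, r))
  })
}

#' F1 recovery (percent)
#'
#' The sum of per-genome F1 scores divided by the theoretical maximum
#' (100 per reference genome); genomes with no assigned bin contribute 0.
#'
#' @param f1_scores Per-genome F1 values on the 0-100 scale.
#' @param n_genomes Number of reference genomes (default
#'   `length(f1_scores)`).
#' @export
f1_recovery <- function(f1_scores, n_genomes = length(f1_scores)) {
  stopifnot(n_genomes >= 1)
  100 * sum(f1_scores) / (100 * n_genomes)
}

#' Evaluate a binning result against a ground truth
#'
#' @inheritParams assignment_matrix
#' @return List of class `bin_evaluation`: `precision`, `recall`, `f1`
#'   (dataset level), `per_genome` (tibble), `median_f1`, `f1_recovery`,
#'   `S`, `unbinned`, `excluded`.
#' @export
evaluate_binning <- function(assignment, truth) {
  am <- assignment_matrix(assignment, truth)
  truth <- tibble::as_tibble(truth)
  if (!"misassembled" %in% names(truth)) truth$misassembled <- FALSE
  kept <- truth[!as.logical(truth$misassembled), , drop = FALSE]
  glen <- tapply(kept$length, kept$genome, sum)
  pg <- per_genome_f1(am$S, glen)
  p <- binning_precision(am$S)
  r <- binning_recall(am$S, am$unbinned)
  structure(
    list(precision = p, recall = r, f1 = binning_f1(p, r),
         per_genome = pg, median_f1 = stats::median(pg$f1),
         f1_recovery = f1_recovery(pg$f1),
         S = am$S, unbinned = am$unbinned, excluded = am$excluded),
    class = "bin_evaluation"
  )
}

#' @export
print.bin_evaluation <- function(x, ...) {
  cat("<bin_evaluation>\n")
  cat(sprintf("  precision %.2f  recall %.2f  F1 %.2f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  %d genomes: median F1 %.2f, F1 recovery %.2f\n",
              nrow(x$per_genome), x$median_f1, x$f1_recovery))
  invisible(x)
}

#' Non-overlapping fraction of genome hulls in an embedding
#'
#' For each genome's points: centroid-distance outliers beyond
#' Q3 + 1.5 IQR (linear-interpolation quartiles) are discarded, a convex
#' hull is built from the survivors, and the hull area t and the area u not
#' covered by any other genome's hull are measured. The dataset statistic
#' is v = 100 * sum(u) / sum(t), the percentage of hull area free of
#' overlap — 100 for perfectly separated genomes, 0 for coincident ones.
#'
#' @param coords Data frame `contig`, `x`, `y`.
#' @param labels Genome label per row of `coords` (or a data frame
#'   `contig`, `genome` to join).
#' @return List of class `hull_stats`: `per_genome` tibble (`genome`, `n`,
#'   `n_kept`, `t`, `u`), `v`, and `skipped` (genomes with fewer than 3
#'   surviving points).
#' @export
nonoverlap_fraction <- function(coords, labels) {
  coords <- tibble::as_tibble(coords)
  if (is.data.frame(labels)) {
    labels <- labels$genome[match(coords$contig, labels$contig)]
  }
  stopifnot(length(labels) == nrow(coords))
  groups <- split(coords[, c("x", "y")], labels)
  if (length(groups) < 2L) stop("need at least 2 genome groups")

  hulls <- list()
  stats_rows <- list()
  skipped <- character()
  for (g in names(groups)) {
    pts <- as.matrix(groups[[g]])
    kept <- hull_filter_outliers(pts)
    if (nrow(kept) < 3L) {
      skipped <- c(skipped, g)
      stats_rows[[g]] <- tibble::tibble(genome = g, n = nrow(pts),
                                        n_kept = nrow(kept), t = NA_real_,
                                        u = NA_real_)
      next
    }
    h <- convex_hull(kept)
    hulls[[g]] <- h
    stats_rows[[g]] <- tibble::tibble(genome = g, n = nrow(pts),
                                      n_kept = nrow(kept),
                                      t = polygon_area(h), u = NA_real_)
  }
  if (length(hulls) == 0L) stop("all genome groups degenerate; no hulls")
  per <- dplyr::bind_rows(stats_rows)
  for (g in names(hulls)) {
    others <- hulls[names(hulls) != g]
    overlap <- if (length(others) == 0L) 0 else
      union_intersection_area(hulls[[g]], others)
    per$u[per$genome == g] <- per$t[per$genome == g] - overlap
  }
  v <- 100 * sum(per$u, na.rm = TRUE) / sum(per$t, na.rm = TRUE)
  structure(list(per_genome = per, v = v, skipped = skipped),
            class = "hull_stats")
}

#' @export
print.hull_stats <- function(x, ...) {
  cat(sprintf("<hull_stats> %d hulls, v = %.2f%%", nrow(x$per_genome), x$v))
  if (length(x$skipped)) cat(" (skipped:", paste(x$skipped, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

hull_filter_outliers <- function(pts) {
  centroid <- colMeans(pts)
  d <- sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2)
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  pts[d <= q[2] + 1.5 * (q[2] - q[1]), , drop = FALSE]
}
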