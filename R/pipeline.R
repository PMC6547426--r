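#' Run the full binning pipeline
#'
#' Stages, in order: kingdom partition by bitscore-filtered LCA taxonomy;
#' 5-mer composition, CLR normalisation, PCA and t-SNE per kingdom pool;
#' marker-guided iterative DBSCAN with optional taxonomic splitting;
#' decision-tree recruitment of the unclustered remainder. Contigs below
#' the length cutoff are excluded before any stage.
#'
#' @param assembly FASTA path, [Biostrings::DNAStringSet], or a
#'   `synthetic_community` (in which case coverage, hits, markers and
#'   taxonomy default to the community's own tables).
#' @param coverage Coverage TSV path or data frame (`contig`, `coverage`);
#'   if `NULL`, SPAdes-style `_cov_` header suffixes are parsed.
#' @param hits Protein homology hits: TSV path or data frame (`qseqid`,
#'   `contig`, `staxid`, `bitscore`).
#' @param markers Marker hits: TSV path or data frame (`contig`,
#'   `marker_id`).
#' @param marker_set Expected marker ids (vector or one-column TSV path);
#'   defaults to the ids observed in `markers`.
#' @param taxonomy A [taxonomy] object, or a directory containing
#'   `nodes.tsv`/`names.tsv` (taxdump dialect).
#' @param length_cutoff Minimum contig length in bp (default 3000).
#' @param kingdom Which kingdom pools to cluster: `"bacteria"`,
#'   `"archaea"` or `"both"`.
#' @param include_unclassified Pool taxonomically unclassified contigs with
#'   Bacteria instead of dropping them (default FALSE).
#' @param config A [cluster_config()]; its seed is overridden by `seed`.
#' @param recruit Run the supervised recruitment stage (default TRUE).
#' @param recruit_cfg A [recruit_config()]; its seed is overridden by
#'   `seed`.
#' @param seed Master seed recorded in the manifest and forwarded to every
#'   stochastic step.
#' @param out_dir Optional output directory: writes `bins.tsv`,
#'   `taxonomy.tsv`, `embedding.tsv`, `recruitment.tsv` and
#'   `manifest.json` (plus per-bin FASTA under `bins/` when
#'   `write_fasta = TRUE`).
#' @param write_fasta Write per-bin FASTA files (default FALSE).
#' @return Object of class `bin_result`; see [tidy.bin_result()] and
#'   [glance.bin_result()].
#' @export
run_pipeline <- function(assembly, coverage = NULL, hits = NULL,
                         markers = NULL, marker_set = NULL, taxonomy = NULL,
                         length_cutoff = 3000,
                         kingdom = c("bacteria", "archaea", "both"),
                         include_unclassified = FALSE,
                         config = cluster_config(), recruit = TRUE,
                         recruit_cfg = recruit_config(), seed = 1,
                         out_dir = NULL, write_fasta = FALSE) {
  kingdom <- match.arg(kingdom)
  if (inherits(assembly, "synthetic_community")) {
    com <- assembly
    seqs <- Biostrings::DNAStringSet(com$contigs$sequence)
    names(seqs) <- com$contigs$contig
    coverage <- coverage %||% com$contigs[, c("contig", "coverage")]
    hits <- hits %||% com$protein_hits
    markers <- markers %||% com$marker_hits
    marker_set <- marker_set %||% com$marker_set
    taxonomy <- taxonomy %||% com$tree
  } else {
    seqs <- if (inherits(assembly, "DNAStringSet")) assembly else
      read_assembly(assembly)
  }
  if (is.character(hits)) hits <- read_protein_hits(hits)
  if (is.character(markers)) markers <- read_marker_hits(markers)
  if (is.character(marker_set) && length(marker_set) == 1L &&
      file.exists(marker_set)) {
    marker_set <- read_marker_set(marker_set)
  }
  if (is.null(marker_set)) marker_set <- sort(unique(markers$marker_id))
  tree <- if (is.character(taxonomy)) {
    read_taxonomy(file.path(taxonomy, "nodes.tsv"),
                  file.path(taxonomy, "names.tsv"))
  } else taxonomy
  stopifnot(inherits(tree, "taxonomy"))
  config$seed <- as.integer(seed)
  recruit_cfg$seed <- as.integer(seed)

  cov <- resolve_coverage(seqs, coverage)
  contigs <- tibble::tibble(contig = names(seqs),
                            length = Biostrings::width(seqs),
                            coverage = cov$coverage)
  # consistency: hits/markers referring to unknown contigs are dropped
  for (nm in c("hits", "markers")) {
    tbl <- get(nm)
    orphan <- !(tbl$contig %in% contigs$contig)
    if (any(orphan)) {
      warning(sum(orphan), " ", nm, " row(s) for contigs absent from the ",
              "assembly dropped")
      assign(nm, tbl[!orphan, , drop = FALSE])
    }
  }

  n_input <- nrow(contigs)
  contigs <- contigs[contigs$length >= length_cutoff, , drop = FALSE]
  if (nrow(contigs) == 0L) stop("no contigs pass the length filter (",
                                length_cutoff, " bp)")
  hits <- hits[hits$contig %in% contigs$contig, , drop = FALSE]
  markers <- markers[markers$contig %in% contigs$contig, , drop = FALSE]

  # stage 1: taxonomy
  prot <- classify_proteins(hits, tree)
  contig_tax <- partition_kingdoms(assign_contig_taxonomy(prot, tree), tree)
  contigs <- dplyr::left_join(contigs,
                              contig_tax[, c("contig", "taxid", "kingdom")],
                              by = "contig")
  contigs$kingdom[is.na(contigs$kingdom)] <- "unclassified"
  contigs$taxid[is.na(contigs$taxid)] <- tree$root

  pools <- switch(kingdom, bacteria = "Bacteria", archaea = "Archaea",
                  both = c("Bacteria", "Archaea"))
  assignments <- list()
  embeddings <- list()
  logs <- list()
  unclustered <- character()
  for (kd in pools) {
    sel <- contigs$kingdom == kd
    if (kd == "Bacteria" && include_unclassified) {
      sel <- sel | contigs$kingdom == "unclassified"
    }
    pool <- contigs[sel, , drop = FALSE]
    if (nrow(pool) < 4L) {
      unclustered <- c(unclustered, pool$contig)
      next
    }
    # stage 2: composition on the kingdom pool
    counts <- count_kmers(seqs[pool$contig])
    pca <- pca_reduce(clr_normalize(counts), dims = 50)
    # stage 3: marker-guided clustering
    cl <- cluster_contigs(pool, pca, markers, marker_set, config, tree)
    asg <- cl$assignment
    asg$recruited <- FALSE
    uncl <- cl$unclustered
    log <- NULL
    # stage 4: recruitment
    if (recruit && nrow(asg) > 0L && length(uncl) > 0L) {
      feats <- build_features(pool, pca, tree,
                              use_taxonomy = recruit_cfg$use_taxonomy)
      rc <- recruit_contigs(asg, uncl, feats, markers, recruit_cfg)
      asg <- rc$assignment
      uncl <- rc$unclustered
      log <- rc$log
    }
    if (nrow(asg) > 0L) asg$kingdom <- kd
    assignments[[kd]] <- asg
    embeddings[[kd]] <- cl$embedding
    if (!is.null(log)) logs[[kd]] <- dplyr::mutate(log, kingdom = kd)
    unclustered <- c(unclustered, uncl)
  }
  assignment <- dplyr::bind_rows(assignments)
  # renumber bins uniquely across kingdom pools
  if (nrow(assignment) > 0L) {
    key <- paste(assignment$kingdom, assignment$bin)
    assignment$bin <- sprintf("bin_%03d", match(key, unique(key)))
    assignment <- rescore_bins(assignment, markers, marker_set)
  }

  res <- structure(
    list(
      assignment = assignment,
      unclustered = unclustered,
      contig_taxonomy = contigs[, c("contig", "length", "coverage",
                                    "taxid", "kingdom")],
      embedding = dplyr::bind_rows(embeddings, .id = "kingdom"),
      recruitment_log = if (length(logs)) dplyr::bind_rows(logs) else NULL,
      marker_set = marker_set,
      params = list(length_cutoff = length_cutoff, kingdom = kingdom,
                    include_unclassified = include_unclassified,
                    config = unclass(config),
                    recruit = recruit, recruit_cfg = unclass(recruit_cfg)),
      counts = c(input = n_input, after_length_filter = nrow(contigs),
                 binned = nrow(assignment),
                 unclustered = length(unclustered)),
      seed = as.integer(seed)
    ),
    class = "bin_result"
  )
  if (!is.null(out_dir)) {
    write_result(res, out_dir,
                 seqs = if (write_fasta) seqs else NULL)
  }
  res
}

# recompute completeness/purity of final bins (recruited contigs included)
rescore_bins <- function(assignment, marker_hits, marker_set) {
  scores <- assignment |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(function(d, key) {
      s <- score_cluster(d$contig, marker_hits, marker_set)
      d$completeness <- s$completeness
      d$purity <- s$purity
      d
    }) |>
    dplyr::ungroup()
  scores
}

#' @export
print.bin_result <- function(x, ...) {
  n_bins <- length(unique(x$assignment$bin))
  cat("<bin_result> ", n_bins, " bins, ", nrow(x$assignment),
      " contigs binned (", sum(x$assignment$recruited %||% FALSE),
      " recruited), ", length(x$unclustered), " unclustered; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

write_result <- function(res, out_dir, seqs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$assignment, file.path(out_dir, "bins.tsv"))
  readr::write_tsv(res$contig_taxonomy, file.path(out_dir, "taxonomy.tsv"))
  readr::write_tsv(res$embedding, file.path(out_dir, "embedding.tsv"))
  if (!is.null(res$recruitment_log)) {
    readr::write_tsv(res$recruitment_log, file.path(out_dir, "recruitment.tsv"))
  }
  manifest <- list(
    package = "markerbin",
    version = as.character(utils::packageVersion("markerbin")),
    seed = res$seed, params = res$params, counts = as.list(res$counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(seqs) && nrow(res$assignment) > 0L) {
    write_bin_fasta(res$assignment, seqs, file.path(out_dir, "bins"))
  }
  invisible(out_dir)
}
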