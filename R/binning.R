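#' Clustering stage configuration
#'
#' @param eps_start First DBSCAN eps value tried (default 0.3).
#' @param eps_step Increment between successive eps values (default 0.1).
#' @param min_samples DBSCAN core-point neighbourhood size (default 4).
#' @param completeness_min,purity_min Cluster acceptance gate in percent
#'   (strictly above 20 / 90 by default).
#' @param max_eps_steps Hard cap on the sweep length so it terminates even
#'   on geometry where a single cluster is never reached (default 50).
#' @param perplexity t-SNE perplexity (default 30).
#' @param tsne_iter t-SNE gradient iterations (default 1000).
#' @param scale_features Standardise the (x, y, coverage) axes before
#'   DBSCAN. Off by default: coverage enters as a raw third dimension, so
#'   eps is interpreted on the embedding/coverage scale.
#' @param taxon_split Recursively split the unclustered remainder by
#'   taxonomy, phylum down to species (default TRUE when a taxonomy is
#'   supplied).
#' @param seed Master seed forwarded to every embedding.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(eps_start = 0.3, eps_step = 0.1, min_samples = 4,
                           completeness_min = 20, purity_min = 90,
                           max_eps_steps = 50, perplexity = 30,
                           tsne_iter = 1000, scale_features = FALSE,
                           taxon_split = TRUE, seed = 1) {
  stopifnot(eps_start > 0, eps_step > 0, min_samples >= 2)
  structure(
    list(eps_start = eps_start, eps_step = eps_step,
         min_samples = min_samples, completeness_min = completeness_min,
         purity_min = purity_min, max_eps_steps = max_eps_steps,
         perplexity = perplexity, tsne_iter = tsne_iter,
         scale_features = scale_features, taxon_split = taxon_split,
         seed = as.integer(seed)),
    class = "cluster_config"
  )
}

points_matrix <- function(points, config) {
  m <- cbind(x = points$x, y = points$y, coverage = points$coverage)
  rownames(m) <- points$contig
  if (isTRUE(config$scale_features)) m <- scale(m)
  m
}

#' Sweep DBSCAN eps values, selecting by median completeness
#'
#' Evaluates eps = start, start + step, ... scoring every cluster against
#' the single-copy markers. The sweep stops once an eps yields at most one
#' cluster (or after `max_eps_steps` values). The clustering kept is the one
#' whose gate-passing clusters have the highest median completeness, ties
#' going to the smaller eps; if no eps produces a gate-passing cluster an
#' empty clustering is returned.
#'
#' @param points Tibble `contig`, `x`, `y`, `coverage`.
#' @param marker_hits Data frame `contig`, `marker_id`.
#' @param marker_set Expected single-copy marker ids.
#' @param config A [cluster_config()].
#' @return List with `clusters` (list of contig-id vectors, gate-passers
#'   and failures alike), `scores`, `passes` (logical per cluster), `eps`,
#'   and `labels` (the winning assignment tibble). `eps` is `NA` when
#'   nothing passed.
#' @export
sweep_eps <- function(points, marker_hits, marker_set, config = cluster_config()) {
  m <- points_matrix(points, config)
  dist_matrix <- as.matrix(stats::dist(m))
  eps_values <- config$eps_start + config$eps_step * (seq_len(config$max_eps_steps) - 1)
  best <- list(median_completeness = -Inf, eps = NA_real_, clusters = list(),
               scores = list(), passes = logical(), labels = NULL)
  for (eps in eps_values) {
    lab <- dbscan_cluster(m, eps = eps, min_samples = config$min_samples,
                          dist_matrix = dist_matrix)
    cl_ids <- sort(unique(lab$cluster[!is.na(lab$cluster)]))
    clusters <- lapply(cl_ids, function(k) lab$id[!is.na(lab$cluster) & lab$cluster == k])
    scores <- lapply(clusters, score_cluster, marker_hits = marker_hits,
                     marker_set = marker_set)
    passes <- vapply(scores, passes_gate, logical(1),
                     completeness_min = config$completeness_min,
                     purity_min = config$purity_min)
    med <- if (any(passes))
      stats::median(vapply(scores[passes], `[[`, numeric(1), "completeness"))
    else -Inf
    if (med > best$median_completeness) {
      best <- list(median_completeness = med, eps = eps, clusters = clusters,
                   scores = scores, passes = passes, labels = lab)
    }
    # "one group": the pool has merged into a single cluster with no noise
    if (length(clusters) == 1L && !anyNA(lab$cluster)) break
  }
  best
}

#' Iterative marker-guided DBSCAN clustering of one contig pool
#'
#' Repeats: sweep eps over the current pool, freeze the gate-passing
#' clusters as bins, and return the failed clusters plus noise to the pool;
#' stops when a round accepts nothing. The embedding coordinates are fixed
#' for the pool (re-embedding happens only when a taxonomic split creates a
#' new pool).
#'
#' @inheritParams sweep_eps
#' @param split_level Provenance label stored on the bins (default
#'   `"none"`).
#' @return List with `bins` (list of lists: `contigs`, `completeness`,
#'   `purity`, `eps`, `round`, `split_level`) and `unclustered` (contig
#'   ids).
#' @export
iterative_cluster <- function(points, marker_hits, marker_set,
                              config = cluster_config(),
                              split_level = "none") {
  bins <- list()
  pool <- points
  round <- 0L
  while (nrow(pool) >= config$min_samples) {
    round <- round + 1L
    sw <- sweep_eps(pool, marker_hits, marker_set, config)
    if (!any(sw$passes)) break
    for (k in which(sw$passes)) {
      bins[[length(bins) + 1L]] <- list(
        contigs = sw$clusters[[k]],
        completeness = sw$scores[[k]]$completeness,
        purity = sw$scores[[k]]$purity,
        eps = sw$eps, round = round, split_level = split_level
      )
    }
    accepted <- unlist(sw$clusters[sw$passes])
    pool <- pool[!(pool$contig %in% accepted), , drop = FALSE]
  }
  list(bins = bins, unclustered = pool$contig)
}

split_ranks <- function() rev(canonical_ranks[canonical_ranks != "superkingdom"])

#' Taxonomic splitting of the unclustered remainder
#'
#' At each level from phylum down to species, partitions the pool by
#' ancestor at that level (contigs with no node at the level are carried
#' forward unsplit), embeds each group afresh from its PCA rows, runs
#' [iterative_cluster()] per group, and pools all leftovers for the next
#' level.
#'
#' @param pool Tibble `contig`, `coverage`, `taxid` for the unclustered
#'   contigs.
#' @param pca PCA score matrix with contig rownames (superset of the pool).
#' @param marker_hits,marker_set,config As in [sweep_eps()].
#' @param tree A [taxonomy] object.
#' @return List with `bins` (as in [iterative_cluster()], with
#'   `split_level` set to the rank used) and `unclustered`.
#' @export
taxon_split_cluster <- function(pool, pca, marker_hits, marker_set, tree,
                                config = cluster_config()) {
  bins <- list()
  current <- pool
  ranks <- split_ranks()
  for (li in seq_along(ranks)) {
    level <- ranks[li]
    if (nrow(current) < config$min_samples) break
    anc <- rank_ancestor(tree, current$taxid, level)
    leftovers <- current[is.na(anc), , drop = FALSE]
    groups <- split(current[!is.na(anc), , drop = FALSE], anc[!is.na(anc)])
    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      if (nrow(grp) < max(4L, config$min_samples)) {
        leftovers <- dplyr::bind_rows(leftovers, grp)
        next
      }
      emb <- embed_tsne(pca[grp$contig, , drop = FALSE],
                        perplexity = config$perplexity,
                        seed = config$seed + 1000L * li + gi,
                        max_iter = config$tsne_iter)
      pts <- dplyr::inner_join(grp, emb, by = "contig")
      res <- iterative_cluster(pts, marker_hits, marker_set, config,
                               split_level = level)
      bins <- c(bins, res$bins)
      leftovers <- dplyr::bind_rows(
        leftovers, grp[grp$contig %in% res$unclustered, , drop = FALSE])
    }
    current <- leftovers
  }
  list(bins = bins, unclustered = current$contig)
}

bins_to_tibble <- function(bins) {
  if (length(bins) == 0L) {
    return(tibble::tibble(bin = character(), contig = character(),
                          completeness = numeric(), purity = numeric(),
                          round = integer(), split_level = character(),
                          eps = numeric()))
  }
  ids <- sprintf("bin_%03d", seq_along(bins))
  purrr::map2_dfr(bins, ids, function(b, id) {
    tibble::tibble(bin = id, contig = b$contigs,
                   completeness = b$completeness, purity = b$purity,
                   round = b$round, split_level = b$split_level, eps = b$eps)
  })
}

#' Cluster kingdom-specific contigs into genome bins
#'
#' The full clustering stage: embed the pool's PCA composition with t-SNE,
#' run marker-guided iterative DBSCAN over (x, y, coverage), and optionally
#' split the unclustered remainder by taxonomy and re-cluster each group.
#'
#' @param contigs Tibble with columns `contig`, `coverage` and, when
#'   taxonomic splitting is wanted, `taxid`.
#' @param pca PCA score matrix with contig rownames covering the pool.
#' @param marker_hits Data frame `contig`, `marker_id`.
#' @param marker_set Expected single-copy marker ids.
#' @param config A [cluster_config()].
#' @param tree Optional [taxonomy] for splitting.
#' @return List with `assignment` (tibble `bin`, `contig`, `completeness`,
#'   `purity`, `round`, `split_level`, `eps`), `unclustered` (contig ids)
#'   and `embedding` (the pool-level t-SNE coordinates).
#' @export
cluster_contigs <- function(contigs, pca, marker_hits, marker_set,
                            config = cluster_config(), tree = NULL) {
  contigs <- tibble::as_tibble(contigs)
  stopifnot(all(c("contig", "coverage") %in% names(contigs)))
  if (nrow(contigs) < 4L) {
    return(list(assignment = bins_to_tibble(list()),
                unclustered = contigs$contig, embedding = NULL))
  }
  emb <- embed_tsne(pca[contigs$contig, , drop = FALSE],
                    perplexity = config$perplexity, seed = config$seed,
                    max_iter = config$tsne_iter)
  pts <- dplyr::inner_join(contigs, emb, by = "contig")
  res <- iterative_cluster(pts, marker_hits, marker_set, config)
  bins <- res$bins
  unclustered <- res$unclustered
  if (isTRUE(config$taxon_split) && !is.null(tree) &&
      "taxid" %in% names(contigs)) {
    pool <- contigs[contigs$contig %in% unclustered, , drop = FALSE]
    ts <- taxon_split_cluster(pool, pca, marker_hits, marker_set, tree, config)
    bins <- c(bins, ts$bins)
    unclustered <- c(setdiff(unclustered, pool$contig), ts$unclustered)
  }
  assignment <- bins_to_tibble(bins)
  if (anyDuplicated(assignment$contig)) {
    stop("internal error: contig assigned to more than one bin")
  }
  list(assignment = assignment, unclustered = unclustered, embedding = emb)
}
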