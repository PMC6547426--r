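#' DBSCAN clustering in low-dimensional Euclidean space
#'
#' Classic density-based clustering: points with at least `min_samples`
#' neighbours within radius `eps` (the point itself included) are core
#' points; clusters are the connected components of core points under the
#' eps-neighbourhood graph; non-core points within eps of a core point are
#' border points and join the cluster of their lowest-id core neighbour
#' (a deterministic tie-break); everything else is noise.
#'
#' @param points Numeric matrix (n x d) with rownames as point ids, or a
#'   data frame whose first column is the id.
#' @param eps Neighbourhood radius.
#' @param min_samples Minimum neighbourhood size for a core point
#'   (default 4).
#' @param dist_matrix Optional precomputed full distance matrix (n x n) in
#'   the same row order, to avoid recomputation across an eps sweep.
#' @return Tibble `id`, `cluster` (integer; `NA` for noise), `core`
#'   (logical). Cluster labels are numbered 1.. in order of their smallest
#'   member id.
#' @export
dbscan_cluster <- function(points, eps, min_samples = 4, dist_matrix = NULL) {
  if (is.data.frame(points)) {
    ids <- as.character(points[[1]])
    m <- as.matrix(points[, -1, drop = FALSE])
  } else {
    m <- points
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  }
  n <- nrow(m)
  stopifnot(n >= 1L, eps > 0, min_samples >= 2)
  # process in ascending id order so border ties are deterministic
  ord <- order(ids)
  if (is.null(dist_matrix)) {
    dist_matrix <- as.matrix(stats::dist(m))
  }
  D <- dist_matrix[ord, ord, drop = FALSE]
  ids_o <- ids[ord]

  A <- D <= eps
  core <- unname(rowSums(A) >= min_samples)
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    next_label <- next_label + 1L
    # BFS over core points through the eps graph
    queue <- i
    labels[i] <- next_label
    while (length(queue) > 0L) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- which(A[p, ] & core & is.na(labels))
      labels[nb] <- next_label
      queue <- c(queue, nb)
    }
  }
  # border points: lowest-id core neighbour's cluster (rows already sorted
  # by id, so the first core neighbour is the lowest id)
  for (i in which(!core)) {
    nb <- which(A[i, ] & core)
    if (length(nb) > 0L) labels[i] <- labels[nb[1]]
  }
  out <- tibble::tibble(id = ids_o, cluster = labels, core = core)
  out[match(ids, out$id), ]
}
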