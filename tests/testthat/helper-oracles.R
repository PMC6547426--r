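# Independent brute-force oracles used to validate the implementations.

# root-to-node path by naive parent chasing on the node table
oracle_path <- function(tree, taxid) {
  nodes <- tree$nodes
  path <- taxid
  while (TRUE) {
    p <- nodes$parent[nodes$taxid == taxid]
    if (p == taxid) break
    path <- c(p, path)
    taxid <- p
  }
  path
}

# LCA as the deepest element of the intersection of root-to-node paths
oracle_lca <- function(tree, a, b) {
  pa <- oracle_path(tree, a)
  pb <- oracle_path(tree, b)
  common <- intersect(pa, pb)
  common[which.max(match(common, pa))]
}

# literal transcription of the majority-vote rule, enumerating ranks and
# checking both conditions on raw paths
oracle_vote <- function(tree, taxids) {
  nodes <- tree$nodes
  at_rank <- function(t, r) {
    p <- oracle_path(tree, t)
    ranks <- nodes$rank[match(p, nodes$taxid)]
    hit <- p[ranks == r]
    if (length(hit) > 0) hit[length(hit)] else NA_integer_
  }
  for (r in c("species", "genus", "family", "order", "class", "phylum",
              "superkingdom")) {
    proj <- vapply(taxids, at_rank, integer(1), r = r)
    voters <- proj[!is.na(proj)]
    if (length(voters) == 0) next
    tab <- table(voters)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) != 1 || max(tab) / length(voters) < 0.5) next
    cand <- winners
    lower <- taxids[is.na(proj)]
    ok <- if (length(lower) == 0) TRUE else {
      anc_of_cand <- oracle_path(tree, cand)
      sum(lower %in% anc_of_cand) * 2 > length(lower)
    }
    if (ok) return(cand)
  }
  Reduce(function(a, b) oracle_lca(tree, a, b), taxids)
}

# brute-force DBSCAN: explicit neighbourhood graph, BFS from core points,
# border points joined to their lowest-id core neighbour's cluster
oracle_dbscan <- function(m, eps, min_samples) {
  ids <- rownames(m)
  ord <- order(ids)
  m <- m[ord, , drop = FALSE]
  ids <- ids[ord]
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2)) <= eps
  }
  core <- colSums(adj) >= min_samples
  label <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(label[i])) next
    cl <- cl + 1L
    frontier <- i
    label[i] <- cl
    while (length(frontier)) {
      nxt <- integer()
      for (p in frontier) {
        for (q in which(adj[p, ])) {
          if (core[q] && is.na(label[q])) {
            label[q] <- cl
            nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  for (i in which(!core)) {
    cn <- which(adj[i, ] & core)
    if (length(cn)) label[i] <- label[cn[1]]
  }
  tibble::tibble(id = ids, cluster = label, core = core)
}

# two integer partitions agree up to label renaming
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(is.na(a) != is.na(b))) return(FALSE)
  ok <- !is.na(a)
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# Monte-Carlo estimate of the non-overlap statistic from point-in-polygon
# tests on the same hulls
mc_nonoverlap <- function(hulls, n_samples = 1e5, seed = 1) {
  in_poly <- function(px, py, poly) {
    n <- nrow(poly)
    j <- c(n, seq_len(n - 1))
    inside <- rep(FALSE, length(px))
    for (k in seq_len(n)) {
      xi <- poly[k, 1]; yi <- poly[k, 2]
      xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    inside
  }
  xs <- range(unlist(lapply(hulls, function(h) h[, 1])))
  ys <- range(unlist(lapply(hulls, function(h) h[, 2])))
  box <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  withr::with_seed(seed, {
    px <- runif(n_samples, xs[1], xs[2])
    py <- runif(n_samples, ys[1], ys[2])
  })
  member <- vapply(hulls, function(h) in_poly(px, py, h),
                   logical(length(px)))
  t_total <- sum(colMeans(member)) * box
  u_total <- sum(vapply(seq_along(hulls), function(g) {
    mean(member[, g] & rowSums(member[, -g, drop = FALSE]) == 0) * box
  }, numeric(1)))
  100 * u_total / t_total
}
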