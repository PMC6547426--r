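# Convex-polygon geometry for the hull-separation statistic.
# Polygons are n x 2 matrices of vertices in counter-clockwise order.

convex_hull <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  # chull returns clockwise order; reverse to CCW
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

polygon_signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(poly) abs(polygon_signed_area(poly))

# Sutherland-Hodgman clipping of a convex subject polygon by a convex clip
# polygon (CCW). Exact for convex-convex intersection.
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == n) 1L else i + 1L, ]
    # keep points on the left of edge a->b
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) - (b[2] - a[2]) * (out[, 1] - a[1])
    keep <- side >= -1e-12
    m <- nrow(out)
    nxt <- c(seq_len(m)[-1], 1L)
    new_pts <- list()
    for (k in seq_len(m)) {
      p <- out[k, ]; q <- out[nxt[k], ]
      if (keep[k]) new_pts[[length(new_pts) + 1L]] <- p
      if (keep[k] != keep[nxt[k]]) {
        # edge crosses the clip line; add the intersection point
        d1 <- side[k]; d2 <- side[nxt[k]]
        t <- d1 / (d1 - d2)
        new_pts[[length(new_pts) + 1L]] <- p + t * (q - p)
      }
    }
    out <- if (length(new_pts) >= 3L) do.call(rbind, new_pts) else NULL
  }
  out
}

intersection_area <- function(polys) {
  cur <- polys[[1]]
  for (p in polys[-1]) {
    cur <- clip_convex(cur, p)
    if (is.null(cur)) return(0)
  }
  polygon_area(cur)
}

# Area of hull covered by the union of other hulls, via inclusion-exclusion
# over intersections (each k-wise intersection of convex sets is convex, so
# repeated clipping is exact). Empty intersections prune their supersets.
union_intersection_area <- function(hull, others) {
  k <- length(others)
  if (k == 0L) return(0)
  total <- 0
  live <- list(list(idx = integer(), poly = hull))
  for (depth in seq_len(k)) {
    nxt <- list()
    for (node in live) {
      start <- if (length(node$idx) == 0L) 1L else max(node$idx) + 1L
      if (start > k) next
      for (j in seq.int(start, k)) {
        inter <- clip_convex(node$poly, others[[j]])
        if (is.null(inter)) next
        a <- polygon_area(inter)
        if (a <= 0) next
        sign <- if (depth %% 2L == 1L) 1 else -1
        total <- total + sign * a
        nxt[[length(nxt) + 1L]] <- list(idx = c(node$idx, j), poly = inter)
      }
    }
    if (length(nxt) == 0L) break
    live <- nxt
  }
  total
}
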