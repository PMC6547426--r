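test_that("precision, recall and F1 match hand computations", {
  S <- matrix(c(8, 0, 2, 6), 2, 2,
              dimnames = list(c("b1", "b2"), c("g1", "g2"))) * 1000
  expect_equal(binning_precision(S), 87.5)
  expect_equal(binning_recall(S, unbinned = 4000), 70)
  expect_equal(binning_f1(87.5, 70), 77.78, tolerance = 1e-4)

  pure <- diag(c(5, 7)) * 1000
  expect_equal(binning_precision(pure), 100)
  expect_equal(binning_recall(pure, 0), 100)
  # single cluster split between two genomes
  expect_equal(binning_precision(matrix(c(5, 5), 1, 2) * 1000), 50)
  expect_equal(binning_recall(matrix(0, 0, 2), 10), 0)
  expect_error(binning_precision(matrix(0, 1, 1)), "undefined")
  expect_equal(binning_f1(0, 0), 0)
  expect_equal(binning_f1(100, 100), 100)
})

test_that("F1 lies between min and max of precision and recall", {
  withr::with_seed(31, {
    p <- runif(200, 0, 100)
    r <- runif(200, 0, 100)
    f <- mapply(binning_f1, p, r)
    expect_true(all(f >= pmin(p, r) - 1e-9 & f <= pmax(p, r) + 1e-9))
  })
})

test_that("merging clusters never raises precision; splitting never raises recall", {
  withr::with_seed(77, {
    for (i in 1:20) {
      M <- sample(2:5, 1); N <- sample(2:5, 1)
      S <- matrix(rpois(M * N, 3) * 1000, M, N)
      if (sum(S) == 0) next
      merged <- rbind(S[1, ] + S[2, ], S[-(1:2), , drop = FALSE])
      expect_lte(binning_precision(merged), binning_precision(S) + 1e-9)
      # split a row in two
      split1 <- floor(S[1, ] / 2)
      split2 <- S[1, ] - split1
      spl <- rbind(split1, split2, S[-1, , drop = FALSE])
      expect_lte(binning_recall(spl, 0), binning_recall(S, 0) + 1e-9)
    }
  })
})

test_that("F1 recovery is the mean F1 over all reference genomes", {
  expect_equal(f1_recovery(c(100, 100, 100)), 100)
  expect_equal(f1_recovery(c(100, 0)), 50)
  expect_equal(f1_recovery(c(77.78, 100, 0)), 59.26, tolerance = 1e-3)
  # a genome with no bin still counts in the denominator
  expect_equal(f1_recovery(c(100, 100), n_genomes = 4), 50)
})

test_that("assignment matrix aggregates lengths and excludes misassemblies", {
  truth <- tibble::tibble(
    contig = c("c1", "c2", "c3", "c4", "c5"),
    genome = c("g1", "g1", "g2", "g2", "g1"),
    length = c(5000, 3000, 2000, 6000, 1000),
    misassembled = c(0L, 0L, 0L, 0L, 1L)
  )
  asg <- tibble::tibble(bin = c("b1", "b1", "b2"),
                        contig = c("c1", "c3", "c4"))
  am <- assignment_matrix(asg, truth)
  expect_equal(am$S["b1", "g1"], 5000)
  expect_equal(am$S["b1", "g2"], 2000)
  expect_equal(am$S["b2", "g2"], 6000)
  expect_equal(am$unbinned, 3000)
  expect_equal(am$excluded, 1000)
  ev <- evaluate_binning(asg, truth)
  expect_equal(ev$precision, 100 * (5 + 6) / 13)
  expect_equal(ev$recall, 100 * (5 + 6) / 16)
  expect_equal(nrow(ev$per_genome), 2)
})

test_that("per-genome F1 picks each genome's best bin", {
  S <- matrix(c(8, 0, 2, 6), 2, 2,
              dimnames = list(c("b1", "b2"), c("g1", "g2"))) * 1000
  pg <- per_genome_f1(S, genome_lengths = c(g1 = 8000, g2 = 12000))
  expect_equal(pg$bin, c("b1", "b2"))
  expect_equal(pg$precision[1], 80)
  expect_equal(pg$recall[1], 100)
  expect_equal(pg$recall[2], 50)
  # unassigned genome scores zero
  S0 <- matrix(c(5, 0), 1, 2, dimnames = list("b1", c("g1", "g2")))
  pg0 <- per_genome_f1(S0, c(g1 = 5, g2 = 5))
  expect_equal(pg0$f1[2], 0)
})

square <- function(x0, y0, s = 2) {
  cbind(x = c(x0, x0 + s, x0 + s, x0), y = c(y0, y0, y0 + s, y0 + s))
}

coords_of <- function(groups) {
  tibble::tibble(
    contig = sprintf("p%02d", seq_len(sum(vapply(groups, nrow, 1L)))),
    x = unlist(lapply(groups, function(g) g[, 1])),
    y = unlist(lapply(groups, function(g) g[, 2]))
  )
}

test_that("hull overlap geometry reproduces exact square arithmetic", {
  # overlapping unit-offset squares: t = 4 each, overlap 1, v = 75
  gs <- list(square(0, 0), square(1, 1))
  co <- coords_of(gs)
  hs <- nonoverlap_fraction(co, rep(c("a", "b"), each = 4))
  expect_equal(hs$per_genome$t, c(4, 4))
  expect_equal(hs$per_genome$u, c(3, 3))
  expect_equal(hs$v, 75)

  # disjoint squares: v = 100
  hs <- nonoverlap_fraction(coords_of(list(square(0, 0), square(5, 5))),
                            rep(c("a", "b"), each = 4))
  expect_equal(hs$v, 100)

  # identical squares: v = 0
  hs <- nonoverlap_fraction(coords_of(list(square(0, 0), square(0, 0))),
                            rep(c("a", "b"), each = 4))
  expect_equal(hs$v, 0)
})

test_that("hull overlap matches a Monte-Carlo area oracle on random groups", {
  for (s in 1:8) {
    k <- withr::with_seed(s, sample(2:5, 1))
    groups <- withr::with_seed(s + 10, lapply(seq_len(k), function(i) {
      c0 <- runif(2, 0, 6)
      cbind(c0[1] + rnorm(25, 0, 1), c0[2] + rnorm(25, 0, 1))
    }))
    co <- coords_of(groups)
    labels <- rep(letters[seq_len(k)], each = 25)
    hs <- nonoverlap_fraction(co, labels)
    hulls <- lapply(split(co[, c("x", "y")], labels), function(d) {
      kept <- markerbin:::hull_filter_outliers(as.matrix(d))
      markerbin:::convex_hull(kept)
    })
    mc <- mc_nonoverlap(hulls, n_samples = 1e5, seed = s)
    expect_equal(hs$v, mc, tolerance = 0.011,
                 label = paste("instance", s))
  }
})

test_that("the outlier filter uses the Q3 + 1.5 IQR centroid-distance rule", {
  pts <- rbind(square(0, 0), c(100, 100))
  kept <- markerbin:::hull_filter_outliers(pts)
  expect_equal(nrow(kept), 4)
  # no outliers among symmetric points
  expect_equal(nrow(markerbin:::hull_filter_outliers(square(0, 0))), 4)
})

test_that("degenerate hull groups are skipped with a record", {
  co <- tibble::tibble(contig = sprintf("p%d", 1:7),
                       x = c(0, 2, 2, 0, 0, 1, 2),
                       y = c(0, 0, 2, 2, 5, 5, 5))
  hs <- nonoverlap_fraction(co, c(rep("a", 4), rep("b", 3)))
  expect_equal(nrow(hs$per_genome), 2)
  # the collinear group has zero area; both hulls valid, b contributes t=0
  expect_true(all(c("a", "b") %in% hs$per_genome$genome))
})
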