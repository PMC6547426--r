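toy_tree <- function() {
  taxonomy(tibble::tibble(
    taxid = 1:7,
    parent = c(1L, 1L, 1L, 2L, 2L, 4L, 4L),
    rank = c("no rank", "superkingdom", "superkingdom", "genus", "genus",
             "species", "species"),
    name = c("root", "A", "B", "gA1", "gA2", "sA1a", "sA1b")
  ))
}

test_that("LCA follows the tree shape", {
  tr <- toy_tree()
  expect_equal(taxon_lca(tr, 6, 6), 6)
  expect_equal(taxon_lca(tr, 6, 7), 4)
  expect_equal(taxon_lca(tr, 6, 5), 2)
  expect_equal(taxon_lca(tr, 6, 3), 1)
  expect_equal(taxon_lca_all(tr, c(6, 7, 5)), 2)
  expect_error(taxon_lca(tr, 6, 99), "unresolvable")
})

test_that("LCA is commutative, idempotent, and an ancestor of both inputs", {
  for (s in 1:10) {
    tr <- random_taxonomy(30, seed = s)
    pairs <- withr::with_seed(s, matrix(sample.int(30, 20, TRUE), ncol = 2))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      l <- taxon_lca(tr, a, b)
      expect_equal(taxon_lca(tr, b, a), l)
      expect_equal(taxon_lca(tr, a, a), a)
      expect_true(is_ancestor(tr, a, l))
      expect_true(is_ancestor(tr, b, l))
    }
  }
})

test_that("LCA matches the path-intersection oracle on random trees", {
  for (s in 1:100) {
    tr <- random_taxonomy(sample(5:50, 1), seed = s)
    n <- nrow(tr$nodes)
    pairs <- withr::with_seed(s + 500, matrix(sample.int(n, 10, TRUE), ncol = 2))
    got <- apply(pairs, 1, function(p) taxon_lca(tr, p[1], p[2]))
    want <- apply(pairs, 1, function(p) oracle_lca(tr, p[1], p[2]))
    expect_equal(got, want)
  }
})

test_that("bitscore filter keeps hits within 10% of the top", {
  h <- tibble::tibble(bitscore = c(100, 95, 89))
  expect_equal(filter_hits(h)$bitscore, c(100, 95))
  expect_equal(nrow(filter_hits(h[1, ])), 1)
  expect_equal(nrow(filter_hits(tibble::tibble(bitscore = c(50, 50, 50)))), 3)
  expect_equal(nrow(filter_hits(h[0, ])), 0)
})

test_that("protein classification takes the LCA of retained hits", {
  tr <- toy_tree()
  one <- tibble::tibble(qseqid = "p1", contig = "c1", staxid = 6L,
                        bitscore = 100)
  expect_equal(classify_proteins(one, tr)$taxid, 6)
  sib <- tibble::tibble(qseqid = "p1", contig = "c1", staxid = c(6L, 7L),
                        bitscore = c(100, 95))
  expect_equal(classify_proteins(sib, tr)$taxid, 4)
  cross <- tibble::tibble(qseqid = "p1", contig = "c1", staxid = c(6L, 3L),
                          bitscore = c(100, 99))
  expect_equal(classify_proteins(cross, tr)$taxid, 1)
  # a hit below the bitscore window must not drag the LCA up
  decoy <- tibble::tibble(qseqid = "p1", contig = "c1", staxid = c(6L, 3L),
                          bitscore = c(100, 50))
  expect_equal(classify_proteins(decoy, tr)$taxid, 6)
  expect_warning(out <- classify_proteins(
    tibble::tibble(qseqid = c("p1", "p2"), contig = "c1",
                   staxid = c(6L, 999L), bitscore = 100), tr),
    "unresolvable")
  expect_equal(nrow(out), 1)
})

test_that("majority vote accepts a species backed by ancestor votes", {
  tr <- toy_tree()
  # two species votes plus one genus-level protein that is an ancestor
  res <- vote_contig_taxonomy(tr, c(6, 6, 4))
  expect_equal(res$taxid, 6)
  expect_equal(res$rank, "species")
  # species vs a different genus: the proviso fails at species, the genus
  # rank ties, and agreement is only reached at the superkingdom rank
  res <- vote_contig_taxonomy(tr, c(6, 5))
  expect_equal(res$rank, "superkingdom")
  expect_equal(res$taxid, 2)
})

test_that("a 50/50 rank tie fails the rank and falls through", {
  tr <- toy_tree()
  res <- vote_contig_taxonomy(tr, c(6, 7))
  # species rank ties 1-1, genus rank agrees on gA1
  expect_equal(res$rank, "genus")
  expect_equal(res$taxid, 4)
  expect_true(any(res$votes$outcome == "tie"))
})

test_that("majority vote matches the literal-rule oracle on random inputs", {
  for (s in 1:100) {
    tr <- random_taxonomy(sample(8:50, 1), seed = s + 200)
    n <- nrow(tr$nodes)
    taxids <- withr::with_seed(s + 900, sample.int(n, sample(1:8, 1), TRUE))
    got <- vote_contig_taxonomy(tr, taxids)$taxid
    expect_equal(got, oracle_vote(tr, taxids),
                 label = paste("seed", s, "taxids", paste(taxids, collapse = ",")))
  }
})

test_that("an accepted ranked vote always satisfies the ancestor proviso", {
  for (s in 1:30) {
    tr <- random_taxonomy(40, seed = s + 40)
    taxids <- withr::with_seed(s, sample.int(40, 6, TRUE))
    res <- vote_contig_taxonomy(tr, taxids)
    if (res$rank %in% canonical_ranks) {
      lower <- taxids[is.na(rank_ancestor(tr, taxids, res$rank))]
      if (length(lower) > 0) {
        n_ok <- sum(vapply(lower, function(t)
          is_ancestor(tr, res$taxid, t), logical(1)))
        expect_true(n_ok * 2 > length(lower))
      }
    }
  }
})

test_that("kingdom partition is disjoint and covering", {
  tr <- toy_tree()
  ct <- tibble::tibble(contig = c("c1", "c2", "c3"),
                       taxid = c(6L, 3L, 1L))
  out <- partition_kingdoms(ct, tr)
  expect_equal(out$kingdom, c("A", "B", "unclassified"))
  expect_equal(sort(out$contig), sort(ct$contig))
  expect_false(anyDuplicated(out$contig) > 0)
})

test_that("taxdump round trip preserves the tree", {
  tr <- simulate_taxonomy(n_phyla = 2)
  dir <- withr::local_tempdir()
  readr::write_tsv(tr$nodes[, c("taxid", "parent", "rank")],
                   file.path(dir, "nodes.tsv"))
  readr::write_tsv(tr$nodes[, c("taxid", "name")],
                   file.path(dir, "names.tsv"))
  re <- read_taxonomy(file.path(dir, "nodes.tsv"), file.path(dir, "names.tsv"))
  expect_equal(re$nodes$taxid, tr$nodes$taxid)
  expect_equal(re$nodes$parent, tr$nodes$parent)
  expect_equal(re$nodes$rank, tr$nodes$rank)
  expect_equal(re$root, tr$root)
  # pipe-delimited taxdump dialect parses identically
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", tr$nodes$taxid,
                     tr$nodes$parent, tr$nodes$rank),
             file.path(dir, "nodes.dmp"))
  re2 <- read_taxonomy(file.path(dir, "nodes.dmp"))
  expect_equal(re2$nodes$parent, tr$nodes$parent)
})

test_that("malformed taxonomies are rejected", {
  expect_error(taxonomy(tibble::tibble(
    taxid = 1:2, parent = c(1L, 3L), rank = c("no rank", "species"))),
    "parent taxid missing")
  expect_error(taxonomy(tibble::tibble(
    taxid = 1:3, parent = c(1L, 3L, 2L), rank = rep("no rank", 3))),
    "cycle")
})
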