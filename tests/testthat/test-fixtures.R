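test_that("the simulated taxonomy has full rank chains and three kingdoms", {
  tr <- simulate_taxonomy(n_phyla = 2)
  sp <- tr$nodes$taxid[tr$nodes$rank == "species"]
  for (r in canonical_ranks) {
    anc <- rank_ancestor(tr, sp, r)
    expect_false(anyNA(anc))
  }
  bact <- species_taxids(tr, "Bacteria")
  euk <- species_taxids(tr, "Eukaryota")
  expect_gte(length(bact), 4)
  expect_equal(length(euk), 1)
  expect_equal(taxon_lca(tr, bact[1], euk[1]), tr$root)
})

test_that("community generation is byte-deterministic under the seed", {
  a <- simulate_community(n_genomes = 2, n_contigs = 10, seed = 5)
  b <- simulate_community(n_genomes = 2, n_contigs = 10, seed = 5)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$protein_hits, b$protein_hits)
  expect_identical(a$marker_hits, b$marker_hits)
  c2 <- simulate_community(n_genomes = 2, n_contigs = 10, seed = 6)
  expect_false(identical(a$contigs$sequence, c2$contigs$sequence))
  # written files identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_community(a, d1); write_community(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("planted structure matches the requested parameters", {
  com <- simulate_community(n_genomes = 3, n_contigs = 40,
                            marker_dropout = 0, coverage_profile = "equal",
                            coverage_mean = 50, seed = 8)
  # zero dropout: every genome carries the full marker complement
  for (g in unique(com$contigs$genome)) {
    ids <- com$contigs$contig[com$contigs$genome == g]
    s <- score_cluster(ids, com$marker_hits, com$marker_set)
    expect_equal(s$completeness, 100)
    expect_equal(s$purity, 100)
  }
  # equal profile: one shared coverage mean
  expect_equal(unique(com$genomes$coverage_mean), 50)
  means <- tapply(com$contigs$coverage, com$contigs$genome, mean)
  expect_true(all(abs(means - 50) / 50 < 0.05))
  # contig lengths respect the cutoff floor
  expect_true(all(com$contigs$length >= 3000))
  # staggered profile: two-fold ladder
  st <- simulate_community(n_genomes = 3, n_contigs = 5,
                           coverage_profile = "staggered", seed = 9)
  expect_equal(st$genomes$coverage_mean, 15 * c(1, 2, 4))
})

test_that("ground truth is recoverable from the emitted tables", {
  com <- simulate_community(n_genomes = 2, n_contigs = 15, seed = 10)
  dir <- withr::local_tempdir()
  write_community(com, dir)
  seqs <- read_assembly(file.path(dir, "assembly.fasta"))
  expect_equal(sort(names(seqs)), sort(com$contigs$contig))
  expect_equal(unname(Biostrings::width(seqs[com$contigs$contig])),
               com$contigs$length)
  truth <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(truth$genome, com$truth$genome)
  cov <- resolve_coverage(seqs, file.path(dir, "coverage.tsv"))
  expect_equal(cov$coverage[match(com$contigs$contig, cov$contig)],
               com$contigs$coverage)
  tr <- read_taxonomy(file.path(dir, "nodes.tsv"), file.path(dir, "names.tsv"))
  expect_equal(tr$nodes$parent, com$tree$nodes$parent)
})

test_that("protein hits point at the source species with decoys below the window", {
  com <- simulate_community(n_genomes = 2, n_contigs = 10, hgt_frac = 0,
                            seed = 12)
  prot <- classify_proteins(com$protein_hits, com$tree)
  ct <- assign_contig_taxonomy(prot, com$tree)
  taxid_of <- stats::setNames(com$genomes$taxid, com$genomes$genome)
  truth_tax <- taxid_of[com$contigs$genome[match(ct$contig, com$contigs$contig)]]
  # every contig classifies to its genome's species or an ancestor of it
  ok <- mapply(function(a, t) is_ancestor(com$tree, t, a), ct$taxid, truth_tax)
  expect_true(all(ok))
  # most contigs hit species level exactly
  expect_gt(mean(ct$taxid == truth_tax), 0.5)
})

test_that("host spike adds eukaryotic contigs that leave bacterial pools", {
  com0 <- simulate_community(n_genomes = 2, n_contigs = 20, seed = 14)
  expect_identical(spike_host(com0, 0), com0)
  com <- spike_host(com0, host_fraction = 0.25)
  expect_equal(length(com$host_contigs), round(0.25 / 0.75 * 40))
  expect_true(all(com$truth$genome[match(com$host_contigs,
                                         com$truth$contig)] == "host"))
  prot <- classify_proteins(com$protein_hits, com$tree)
  part <- partition_kingdoms(assign_contig_taxonomy(prot, com$tree), com$tree)
  host_kingdoms <- part$kingdom[part$contig %in% com$host_contigs]
  expect_true(all(host_kingdoms != "Bacteria"))
  expect_true(all(part$kingdom[!(part$contig %in% com$host_contigs)] == "Bacteria"))
})

test_that("composition separability rises with Dirichlet disparity", {
  # near-identical strains (high concentration) separate worse end-to-end
  # than well-separated genomes (concentration 1)
  sep_score <- function(concentration, seed) {
    com <- simulate_community(n_genomes = 2, n_contigs = 60,
                              coverage_profile = "equal",
                              concentration = concentration, seed = seed)
    seqs <- Biostrings::DNAStringSet(com$contigs$sequence)
    names(seqs) <- com$contigs$contig
    emb <- compose_contigs(seqs, seed = 99)$embedding
    xy <- as.matrix(emb[, c("x", "y")])
    genome <- com$contigs$genome[match(emb$contig, com$contigs$contig)]
    cents <- rowsum(xy, genome) / as.vector(table(genome))
    mean(stats::dist(cents)) /
      mean(sqrt(rowSums((xy - cents[genome, ])^2)))
  }
  expect_gt(sep_score(1, 33), sep_score(50, 33))
})
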