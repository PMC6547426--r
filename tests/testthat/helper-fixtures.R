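# Shared fixtures, built once per test run. Heavy objects (communities,
# pipeline runs) are memoised so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

# small community for unit-level checks
small_community <- function() {
  memo("small", simulate_community(n_genomes = 3, n_contigs = 80, seed = 7))
}

# the default study community: 5 staggered genomes, 10% marker dropout,
# 30% eukaryotic host spike
default_community <- function() {
  memo("default", {
    com <- simulate_community(seed = 101)
    spike_host(com, host_fraction = 0.3)
  })
}

default_run <- function() {
  memo("default_run",
       suppressWarnings(run_pipeline(default_community(), seed = 42)))
}

# repeat run for the determinism contract
default_run_again <- function() {
  memo("default_run2",
       suppressWarnings(run_pipeline(default_community(), seed = 42)))
}

# recruitment scenario: 4 well-separated genomes plus a near-identical
# strain pair (shared Markov model) at equal coverage; 20% of every
# genome's contigs withheld from clustering
recruit_scenario <- function() {
  memo("recruit_scenario", {
    strain_model <- withr::with_seed(55, markerbin:::markov_model(3, 1))
    mods <- c(lapply(1:4, function(i)
      withr::with_seed(60 + i, markerbin:::markov_model(3, 1))),
      list(strain_model, strain_model))
    com <- simulate_community(n_genomes = 6, n_contigs = 150,
                              coverage_profile = "equal", models = mods,
                              seed = 103)
    seqs <- Biostrings::DNAStringSet(com$contigs$sequence)
    names(seqs) <- com$contigs$contig
    pca <- pca_reduce(clr_normalize(count_kmers(seqs)), dims = 50)
    pool <- com$contigs[, c("contig", "coverage")]
    withheld <- withr::with_seed(99, unlist(lapply(
      split(pool$contig, com$contigs$genome),
      function(x) sample(x, round(0.2 * length(x)))), use.names = FALSE))
    kept <- pool[!(pool$contig %in% withheld), ]
    cl <- cluster_contigs(kept, pca, com$marker_hits, com$marker_set,
                          cluster_config(taxon_split = FALSE, seed = 21))
    asg <- cl$assignment
    asg$recruited <- FALSE
    feats <- build_features(pool, pca)
    rc <- recruit_contigs(asg, c(cl$unclustered, withheld), feats,
                          com$marker_hits, recruit_config(seed = 21))
    list(com = com, pca = pca, withheld = withheld, before = asg, after = rc)
  })
}

# random toy taxonomy: node 1 is the root; every other node picks an
# earlier parent; ranks drawn from the canonical set plus "no rank"
random_taxonomy <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n_nodes, function(i)
      sample.int(i - 1L, 1L), integer(1)))
    taxonomy(tibble::tibble(
      taxid = seq_len(n_nodes), parent = parent,
      rank = c("no rank", sample(c(canonical_ranks, "no rank"),
                                 n_nodes - 1L, replace = TRUE))
    ))
  })
}

# map each bin to the genome contributing most of its clustered contigs
bin_genome_map <- function(assignment, truth) {
  truth_of <- stats::setNames(truth$genome, truth$contig)
  vapply(split(assignment$contig, assignment$bin), function(x)
    names(which.max(table(truth_of[x]))), character(1))
}
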