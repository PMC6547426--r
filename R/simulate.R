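#' Simulate a toy taxonomy in taxdump dialect
#'
#' Builds a rooted tree with Bacteria, Archaea and Eukaryota superkingdoms
#' and complete canonical rank chains (phylum, class, order, family, genus,
#' species) below each. Every bacterial phylum holds one class/order/family
#' chain with `n_genera` genera of `n_species` species each; Archaea and
#' Eukaryota each get one chain (the eukaryotic species serves as a host
#' genome for spike-in scenarios).
#'
#' @param n_phyla Bacterial phyla (default 3).
#' @param n_genera Genera per bacterial phylum (default 2).
#' @param n_species Species per genus (default 2).
#' @return A [taxonomy] object.
#' @export
simulate_taxonomy <- function(n_phyla = 3, n_genera = 2, n_species = 2) {
  stopifnot(n_phyla >= 1)
  rows <- list(list(1L, 1L, "no rank", "root"),
               list(2L, 1L, "superkingdom", "Bacteria"),
               list(3L, 1L, "superkingdom", "Archaea"),
               list(4L, 1L, "superkingdom", "Eukaryota"))
  nid <- 4L
  add <- function(parent, rank, name) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- list(nid, parent, rank, name)
    nid
  }
  chain <- function(parent, prefix, n_gen, n_sp) {
    ph <- add(parent, "phylum", paste0(prefix, "_phylum"))
    cl <- add(ph, "class", paste0(prefix, "_class"))
    or <- add(cl, "order", paste0(prefix, "_order"))
    fa <- add(or, "family", paste0(prefix, "_family"))
    for (g in seq_len(n_gen)) {
      ge <- add(fa, "genus", paste0(prefix, "_genus", g))
      for (s in seq_len(n_sp)) {
        add(ge, "species", paste0(prefix, "_genus", g, "_sp", s))
      }
    }
    ph
  }
  for (p in seq_len(n_phyla)) chain(2L, paste0("Bac", p), n_genera, n_species)
  chain(3L, "Arc1", 1L, 1L)
  chain(4L, "Euk1", 1L, 1L)
  nodes <- tibble::tibble(
    taxid = vapply(rows, function(r) r[[1]], integer(1)),
    parent = vapply(rows, function(r) r[[2]], integer(1)),
    rank = vapply(rows, function(r) r[[3]], character(1)),
    name = vapply(rows, function(r) r[[4]], character(1))
  )
  taxonomy(nodes)
}

#' Species taxids under a superkingdom
#' @param tree A [taxonomy].
#' @param kingdom Superkingdom name, e.g. `"Bacteria"`.
#' @export
species_taxids <- function(tree, kingdom = "Bacteria") {
  sp <- tree$nodes$taxid[tree$nodes$rank == "species"]
  sk <- rank_ancestor(tree, sp, "superkingdom")
  nm <- tree$nodes$name[unname(tree$index[as.character(sk)])]
  sp[nm == kingdom]
}

# order-k Markov transition matrix (4^k states x 4), rows Dirichlet(conc)
markov_model <- function(order = 3, concentration = 1) {
  n_states <- 4L^order
  g <- matrix(stats::rgamma(n_states * 4L, shape = concentration), n_states, 4L)
  g / rowSums(g)
}

# sample a sequence from an order-k chain given row-wise cumulative probs
markov_sequence <- function(len, cum, order) {
  n_states <- nrow(cum)
  out <- integer(len)
  state <- sample.int(n_states, 1L)
  u <- stats::runif(len)
  base_mod <- n_states %/% 4L
  for (i in seq_len(len)) {
    b <- if (u[i] < cum[state, 1L]) 1L else if (u[i] < cum[state, 2L]) 2L
         else if (u[i] < cum[state, 3L]) 3L else 4L
    out[i] <- b
    state <- ((state - 1L) %% base_mod) * 4L + b
  }
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

#' Simulate a labelled synthetic metagenome community
#'
#' Generates, under one master seed, everything the binning pipeline
#' consumes: contigs with known genome of origin (each genome an order-3
#' Markov model with Dirichlet-sampled transition rows, so genomes differ
#' in k-mer composition), per-contig coverage, planted single-copy marker
#' hits, synthetic protein homology hits pointing at each genome's species
#' taxid (with decoy and horizontally-transferred off-target hits), and a
#' toy taxonomy.
#'
#' @param n_genomes Number of genomes (default 5).
#' @param n_contigs Contigs per genome (default 300).
#' @param length_meanlog,length_sdlog Lognormal contig length parameters
#'   (default meanlog log(4500), sdlog 0.45).
#' @param min_length Contig length floor in bp (default 3000, the assembly
#'   cutoff the pipeline applies).
#' @param coverage_profile `"staggered"` (two-fold ladder of genome means
#'   starting at `coverage_base`) or `"equal"` (all genomes at
#'   `coverage_mean`).
#' @param coverage_base,coverage_mean Coverage scale parameters (defaults
#'   15 and 50).
#' @param coverage_sdlog Per-contig lognormal depth noise around the genome
#'   mean (default 0.08, GC-bias-scale variation for >= 3 kb contigs).
#' @param n_markers Size of the single-copy marker set (default 100).
#' @param marker_dropout Fraction of each genome's marker complement
#'   missing (default 0.1), emulating incomplete genomes.
#' @param hgt_frac Fraction of proteins whose hits point at another
#'   genome's taxid (default 0.02).
#' @param concentration Dirichlet concentration of the Markov rows;
#'   1 gives well-separated compositions, large values (e.g. 50) give
#'   near-identical strain-like genomes.
#' @param models Optional list of transition matrices, recycled across
#'   genomes, to force shared composition between genomes.
#' @param taxids Optional species taxids (one per genome); defaults to
#'   bacterial species spread round-robin across phyla.
#' @param tree Optional [taxonomy]; defaults to [simulate_taxonomy()] sized
#'   to fit the genomes.
#' @param seed Master seed; identical seeds reproduce the community
#'   byte-for-byte.
#' @return Object of class `synthetic_community`: list with `contigs`
#'   (tibble `contig`, `genome`, `length`, `coverage`, `sequence`),
#'   `genomes`, `marker_hits`, `marker_set`, `protein_hits`, `tree`,
#'   `truth` and `seed`.
#' @export
simulate_community <- function(n_genomes = 5, n_contigs = 300,
                               length_meanlog = log(4500),
                               length_sdlog = 0.45, min_length = 3000,
                               coverage_profile = c("staggered", "equal"),
                               coverage_base = 15, coverage_mean = 50,
                               coverage_sdlog = 0.08, n_markers = 100,
                               marker_dropout = 0.1, hgt_frac = 0.02,
                               concentration = 1, models = NULL,
                               taxids = NULL, tree = NULL, seed = 1) {
  coverage_profile <- match.arg(coverage_profile)
  stopifnot(n_genomes >= 1, n_contigs >= 1)
  if (is.null(tree)) {
    tree <- simulate_taxonomy(n_phyla = max(3, ceiling(n_genomes / 4)),
                              n_genera = 2, n_species = 2)
  }
  if (is.null(taxids)) {
    sp <- species_taxids(tree, "Bacteria")
    if (length(sp) < n_genomes) stop("taxonomy too small for ", n_genomes,
                                     " genomes; supply a larger tree")
    # spread genomes round-robin across phyla, as in a mixed community
    phyla <- rank_ancestor(tree, sp, "phylum")
    taxids <- unlist(lapply(seq_len(max(table(phyla))), function(i) {
      vapply(split(sp, phyla), function(s)
        if (length(s) >= i) s[i] else NA_integer_, integer(1))
    }))
    taxids <- taxids[!is.na(taxids)][seq_len(n_genomes)]
  }
  stopifnot(length(taxids) == n_genomes)
  marker_set <- sprintf("marker_%03d", seq_len(n_markers))

  withr::with_seed(as.integer(seed), {
    genome_ids <- sprintf("genome_%02d", seq_len(n_genomes))
    mods <- if (is.null(models)) {
      lapply(seq_len(n_genomes), function(i) markov_model(3, concentration))
    } else {
      rep(models, length.out = n_genomes)
    }
    cov_means <- switch(coverage_profile,
      staggered = coverage_base * 2^(seq_len(n_genomes) - 1),
      equal = rep(coverage_mean, n_genomes)
    )

    contig_rows <- vector("list", n_genomes)
    marker_rows <- vector("list", n_genomes)
    for (gi in seq_len(n_genomes)) {
      lens <- pmax(round(stats::rlnorm(n_contigs, length_meanlog,
                                       length_sdlog)), min_length)
      cum <- t(apply(mods[[gi]], 1, cumsum))
      seqs <- vapply(lens, markov_sequence, character(1), cum = cum,
                     order = 3)
      covs <- cov_means[gi] * stats::rlnorm(n_contigs, -coverage_sdlog^2 / 2,
                                            coverage_sdlog)
      ids <- sprintf("%s_c%04d", genome_ids[gi], seq_len(n_contigs))
      contig_rows[[gi]] <- tibble::tibble(
        contig = ids, genome = genome_ids[gi], length = lens,
        coverage = covs, sequence = seqs
      )
      kept <- marker_set[stats::runif(n_markers) >= marker_dropout]
      marker_rows[[gi]] <- tibble::tibble(
        contig = sample(ids, length(kept), replace = TRUE),
        marker_id = kept
      )
    }
    contigs <- dplyr::bind_rows(contig_rows)
    marker_hits <- dplyr::bind_rows(marker_rows)
    protein_hits <- simulate_protein_hits(contigs, taxids, tree, hgt_frac)

    structure(
      list(
        contigs = contigs,
        genomes = tibble::tibble(genome = genome_ids, taxid = taxids,
                                 coverage_mean = cov_means),
        models = mods,
        marker_hits = marker_hits, marker_set = marker_set,
        protein_hits = protein_hits, tree = tree,
        truth = tibble::tibble(contig = contigs$contig,
                               genome = contigs$genome,
                               length = contigs$length, misassembled = 0L),
        seed = as.integer(seed)
      ),
      class = "synthetic_community"
    )
  })
}

# synthetic homology hits: ~1 protein per 3 kbp; each protein gets a top
# hit at its (possibly HGT-swapped) source species, often a near-top hit at
# a sibling species (driving the LCA to genus), and a decoy hit far below
# the bitscore window
simulate_protein_hits <- function(contigs, taxids, tree, hgt_frac) {
  all_species <- tree$nodes$taxid[tree$nodes$rank == "species"]
  taxid_of <- stats::setNames(taxids, unique(contigs$genome))
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    n_prot <- max(1L, contigs$length[i] %/% 3000L)
    src <- taxid_of[[contigs$genome[i]]]
    prot_rows <- vector("list", n_prot)
    for (p in seq_len(n_prot)) {
      tx <- src
      if (length(taxids) > 1L && stats::runif(1) < hgt_frac) {
        tx <- sample(setdiff(taxids, src), 1L)
      }
      b <- stats::runif(1, 300, 800)
      hit_tax <- tx
      hit_score <- b
      if (stats::runif(1) < 0.5) {
        sib <- sibling_species(tree, tx, all_species)
        hit_tax <- c(hit_tax, sib)
        hit_score <- c(hit_score, stats::runif(1, 0.92, 0.999) * b)
      }
      decoy <- sample(setdiff(all_species, tx), 1L)
      hit_tax <- c(hit_tax, decoy)
      hit_score <- c(hit_score, 0.5 * b)
      prot_rows[[p]] <- tibble::tibble(
        qseqid = sprintf("%s_p%03d", contigs$contig[i], p),
        contig = contigs$contig[i],
        staxid = hit_tax, bitscore = hit_score
      )
    }
    rows[[i]] <- dplyr::bind_rows(prot_rows)
  }
  dplyr::bind_rows(rows)
}

sibling_species <- function(tree, taxid, all_species) {
  g <- rank_ancestor(tree, taxid, "genus")
  sibs <- all_species[rank_ancestor(tree, all_species, "genus") == g &
                        all_species != taxid]
  if (length(sibs) == 0L) taxid else sibs[1L]
}

#' Spike a eukaryotic host into a synthetic community
#'
#' Adds contigs drawn from a distinct host Markov model, assigned to the
#' eukaryotic species of the toy taxonomy, with protein hits pointing at
#' eukaryotic taxa and no bacterial markers; the ground truth labels them
#' `"host"`.
#'
#' @param community A [simulate_community()] result.
#' @param host_fraction Fraction of the final contig set that is host
#'   (0 <= f < 1; default 0.3).
#' @param host_coverage Mean host coverage (default 40).
#' @param seed Seed for the host draws.
#' @return The augmented `synthetic_community`.
#' @export
spike_host <- function(community, host_fraction = 0.3, host_coverage = 40,
                       seed = community$seed + 1L) {
  stopifnot(host_fraction >= 0, host_fraction < 1)
  if (host_fraction == 0) return(community)
  tree <- community$tree
  host_tax <- species_taxids(tree, "Eukaryota")
  if (length(host_tax) == 0L) stop("taxonomy has no eukaryotic species")
  host_tax <- host_tax[1L]
  n_existing <- nrow(community$contigs)
  n_host <- round(host_fraction / (1 - host_fraction) * n_existing)

  withr::with_seed(as.integer(seed), {
    model <- markov_model(3, 1)
    cum <- t(apply(model, 1, cumsum))
    lens <- pmax(round(stats::rlnorm(n_host, log(4500), 0.45)), 3000L)
    seqs <- vapply(lens, markov_sequence, character(1), cum = cum, order = 3)
    covs <- host_coverage * stats::rlnorm(n_host, -0.08^2 / 2, 0.08)
    ids <- sprintf("host_c%04d", seq_len(n_host))
    host_contigs <- tibble::tibble(contig = ids, genome = "host",
                                   length = lens, coverage = covs,
                                   sequence = seqs)
    host_hits <- simulate_protein_hits(host_contigs, host_tax, tree,
                                       hgt_frac = 0)
  })

  community$contigs <- dplyr::bind_rows(community$contigs, host_contigs)
  community$protein_hits <- dplyr::bind_rows(community$protein_hits, host_hits)
  community$truth <- dplyr::bind_rows(
    community$truth,
    tibble::tibble(contig = ids, genome = "host", length = lens,
                   misassembled = 0L)
  )
  community$host_contigs <- ids
  community
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", nrow(x$genomes), " genomes, ",
      nrow(x$contigs), " contigs (",
      round(sum(x$contigs$length) / 1e6, 1), " Mbp), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic community to a directory in the pipeline's dialects
#'
#' Emits `assembly.fasta`, `coverage.tsv`, `hits.tsv`, `markers.tsv`,
#' `marker_set.tsv`, `nodes.tsv`, `names.tsv` and `truth.tsv`.
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(community$contigs$sequence)
  names(seqs) <- community$contigs$contig
  Biostrings::writeXStringSet(seqs, file.path(dir, "assembly.fasta"))
  readr::write_tsv(community$contigs[, c("contig", "coverage")],
                   file.path(dir, "coverage.tsv"))
  readr::write_tsv(community$protein_hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(community$marker_hits, file.path(dir, "markers.tsv"))
  readr::write_tsv(tibble::tibble(marker_id = community$marker_set),
                   file.path(dir, "marker_set.tsv"))
  readr::write_tsv(community$tree$nodes[, c("taxid", "parent", "rank")],
                   file.path(dir, "nodes.tsv"))
  readr::write_tsv(community$tree$nodes[, c("taxid", "name")],
                   file.path(dir, "names.tsv"))
  readr::write_tsv(community$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
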