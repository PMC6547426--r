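#' Canonical taxonomic ranks, most specific first
#'
#' The rank ladder used for contig-level voting (species upward) and for
#' taxonomic splitting during clustering (phylum downward). "superkingdom"
#' is the taxdump-dialect spelling of the kingdom level (Bacteria, Archaea,
#' Eukaryota).
#' @export
canonical_ranks <- c(
  "species", "genus", "family", "order", "class", "phylum", "superkingdom"
)

#' Build a taxonomy tree from a node table
#'
#' @param nodes A data frame with columns `taxid`, `parent`, `rank` and
#'   optionally `name`. Exactly one node must be its own parent (the root).
#'   Rank labels outside [canonical_ranks] are kept verbatim and treated as
#'   "no rank" intermediates.
#' @return A `taxonomy` object supporting ancestor queries, rank projection
#'   and lowest-common-ancestor computation.
#' @export
taxonomy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("taxid", "parent", "rank") %in% names(nodes)))
  if (!"name" %in% names(nodes)) nodes$name <- as.character(nodes$taxid)
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$taxid)) stop("duplicated taxids in node table")

  idx <- stats::setNames(seq_len(nrow(nodes)), as.character(nodes$taxid))
  parent_idx <- unname(idx[as.character(nodes$parent)])
  if (anyNA(parent_idx)) {
    bad <- nodes$taxid[is.na(parent_idx)]
    stop("parent taxid missing from tree for node(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  root_rows <- which(parent_idx == seq_len(nrow(nodes)))
  if (length(root_rows) != 1L) {
    stop("taxonomy must have exactly one root (node that is its own parent)")
  }

  # depth by repeated parent hops; a node further than n hops from the root
  # implies a cycle
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[root_rows] <- 0L
  frontier <- root_rows
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    kids <- which(parent_idx %in% frontier & is.na(depth))
    depth[kids] <- d
    frontier <- kids
    if (d > n) stop("cycle detected in taxonomy")
  }
  if (anyNA(depth)) stop("cycle detected in taxonomy (unreachable nodes)")

  structure(
    list(nodes = nodes, index = idx, parent_idx = parent_idx,
         depth = depth, root = nodes$taxid[root_rows]),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      ", max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Read a taxonomy in NCBI taxdump dialect
#'
#' Accepts `nodes.dmp`-like (taxid | parent | rank) and `names.dmp`-like
#' (taxid | name) tables, either pipe-delimited with optional tab padding
#' (classic taxdump) or plain TSV; the delimiter is auto-detected. Extra
#' columns beyond the ones used are ignored.
#'
#' @param nodes_file,names_file Paths to the node and name tables.
#' @param merged_file Optional two-column table remapping merged (old) taxids
#'   to their current ids.
#' @return A [taxonomy] object; the merged-id map, if given, is attached as
#'   attribute `merged`.
#' @export
read_taxonomy <- function(nodes_file, names_file = NULL, merged_file = NULL) {
  nd <- read_dmp(nodes_file)
  nodes <- tibble::tibble(
    taxid = as.integer(nd[[1]]),
    parent = as.integer(nd[[2]]),
    rank = trimws(nd[[3]])
  )
  if (!is.null(names_file)) {
    nm <- read_dmp(names_file)
    name_tbl <- tibble::tibble(taxid = as.integer(nm[[1]]),
                               name = trimws(nm[[2]]))
    # classic names.dmp repeats taxids for synonyms; prefer scientific name
    # rows when a class column is present, else first occurrence
    if (ncol(nm) >= 4) {
      cls <- trimws(nm[[4]])
      name_tbl <- name_tbl[order(cls != "scientific name"), ]
    }
    name_tbl <- name_tbl[!duplicated(name_tbl$taxid), ]
    nodes <- dplyr::left_join(nodes, name_tbl, by = "taxid")
    nodes$name[is.na(nodes$name)] <- as.character(nodes$taxid[is.na(nodes$name)])
  }
  tree <- taxonomy(nodes)
  if (!is.null(merged_file)) {
    mg <- read_dmp(merged_file)
    attr(tree, "merged") <- stats::setNames(as.integer(mg[[2]]),
                                            as.character(as.integer(mg[[1]])))
  }
  tree
}

# taxdump files are "a<TAB>|<TAB>b<TAB>|..." or plain TSV; normalise both
read_dmp <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl("|", lines, fixed = TRUE))) {
    lines <- sub("\\s*\\|\\s*$", "", lines)
    parts <- strsplit(lines, "\\s*\\|\\s*")
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
  }
  # tolerate a header row (e.g. "taxid<TAB>parent<TAB>rank")
  if (length(parts) > 0L && is.na(suppressWarnings(as.integer(parts[[1]][1])))) {
    parts <- parts[-1]
  }
  ncol <- max(lengths(parts))
  cols <- lapply(seq_len(ncol), function(j)
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_, ""))
  tibble::as_tibble(stats::setNames(cols, paste0("V", seq_len(ncol))))
}

taxon_row <- function(tree, taxid, context = "taxid") {
  i <- unname(tree$index[as.character(taxid)])
  if (anyNA(i)) {
    stop("unresolvable ", context, ": ",
         paste(taxid[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Lowest common ancestor of two taxa
#'
#' @param tree A [taxonomy] object.
#' @param a,b Taxids resolvable in `tree`.
#' @return The taxid of the deepest node that is an ancestor-or-self of both.
#' @export
taxon_lca <- function(tree, a, b) {
  i <- taxon_row(tree, a)
  j <- taxon_row(tree, b)
  while (tree$depth[i] > tree$depth[j]) i <- tree$parent_idx[i]
  while (tree$depth[j] > tree$depth[i]) j <- tree$parent_idx[j]
  while (i != j) {
    i <- tree$parent_idx[i]
    j <- tree$parent_idx[j]
  }
  tree$nodes$taxid[i]
}

#' Reduce a set of taxids to their common LCA
#' @inheritParams taxon_lca
#' @param taxids One or more taxids.
#' @return A single taxid.
#' @export
taxon_lca_all <- function(tree, taxids) {
  Reduce(function(a, b) taxon_lca(tree, a, b), taxids)
}

#' Is `ancestor` an ancestor-or-self of `taxid`?
#' @inheritParams taxon_lca
#' @param taxid,ancestor Taxids resolvable in `tree`.
#' @export
is_ancestor <- function(tree, taxid, ancestor) {
  i <- taxon_row(tree, taxid)
  j <- taxon_row(tree, ancestor)
  while (tree$depth[i] > tree$depth[j]) i <- tree$parent_idx[i]
  i == j
}

#' Project taxids to their ancestor at a given rank
#'
#' @inheritParams taxon_lca
#' @param taxids Vector of taxids.
#' @param rank A single rank label, e.g. `"genus"`.
#' @return Integer vector of ancestor taxids at `rank`; `NA` where a lineage
#'   has no node at that rank.
#' @export
rank_ancestor <- function(tree, taxids, rank) {
  uniq <- unique(as.integer(taxids))
  res <- vapply(uniq, function(t) {
    i <- taxon_row(tree, t)
    repeat {
      if (identical(tree$nodes$rank[i], rank)) return(tree$nodes$taxid[i])
      if (tree$parent_idx[i] == i) return(NA_integer_)
      i <- tree$parent_idx[i]
    }
  }, integer(1))
  unname(res[match(as.integer(taxids), uniq)])
}

#' Full lineage of a taxid
#' @inheritParams taxon_lca
#' @param taxid A single taxid.
#' @return Tibble of the root-to-node path with columns `taxid`, `rank`,
#'   `name`.
#' @export
taxon_lineage <- function(tree, taxid) {
  i <- taxon_row(tree, taxid)
  path <- i
  while (tree$parent_idx[i] != i) {
    i <- tree$parent_idx[i]
    path <- c(i, path)
  }
  tree$nodes[path, c("taxid", "rank", "name")]
}

#' Filter homology hits to those near the top bitscore
#'
#' Retains, within one protein's hit list, the hits whose bitscore is within
#' `top_frac` of the best hit (bitscore >= (1 - top_frac) * max).
#'
#' @param hits Data frame with at least a `bitscore` column.
#' @param top_frac Fraction below the top bitscore still retained
#'   (default 0.10).
#' @return The retained rows, as a tibble.
#' @export
filter_hits <- function(hits, top_frac = 0.10) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) return(hits)
  dplyr::filter(hits, .data$bitscore >= (1 - top_frac) * max(.data$bitscore))
}

#' Classify proteins by bitscore-filtered LCA
#'
#' For every protein, hits within `top_frac` of its top bitscore are kept and
#' the LCA of their subject taxids becomes the protein's taxid. Hits whose
#' subject taxid is not in the tree are dropped (after applying the merged-id
#' remap when the tree carries one) with a warning reporting the count.
#'
#' @param hits Data frame with columns `qseqid`, `contig`, `staxid`,
#'   `bitscore`.
#' @param tree A [taxonomy] object.
#' @param top_frac Bitscore window fraction (default 0.10).
#' @return Tibble with columns `qseqid`, `contig`, `taxid` (one row per
#'   classified protein).
#' @export
classify_proteins <- function(hits, tree, top_frac = 0.10) {
  hits <- tibble::as_tibble(hits)
  stopifnot(all(c("qseqid", "contig", "staxid", "bitscore") %in% names(hits)))
  merged <- attr(tree, "merged")
  if (!is.null(merged)) {
    m <- merged[as.character(hits$staxid)]
    hits$staxid <- ifelse(is.na(m), hits$staxid, unname(m))
  }
  ok <- as.character(hits$staxid) %in% names(tree$index)
  if (any(!ok)) {
    warning(sum(!ok), " hit(s) with unresolvable subject taxid dropped")
    hits <- hits[ok, ]
  }
  if (nrow(hits) == 0L) {
    return(tibble::tibble(qseqid = character(), contig = character(),
                          taxid = integer()))
  }
  hits |>
    dplyr::group_by(.data$qseqid, .data$contig) |>
    dplyr::filter(.data$bitscore >= (1 - top_frac) * max(.data$bitscore)) |>
    dplyr::summarise(taxid = taxon_lca_all(tree, .data$staxid),
                     .groups = "drop")
}

#' Modified majority vote over one contig's protein taxids
#'
#' Ranks are considered from species upward. At each rank every protein
#' taxid is projected to its ancestor at that rank; proteins with no node at
#' that rank count as "lower specificity" and abstain. A candidate is
#' accepted when it is the unique most-voted taxon, carries at least half of
#' the non-abstaining votes, and a strict majority of the abstaining
#' proteins' taxids are ancestors-or-self of it (vacuously true with no
#' abstainers). If no rank yields an answer the plain LCA of all protein
#' taxids is returned.
#'
#' @param tree A [taxonomy] object.
#' @param protein_taxids Non-empty vector of protein-level taxids.
#' @return List with `taxid`, `rank` (a canonical rank, or `"lca"` for the
#'   fallback) and `votes`, a tibble of per-rank diagnostics (candidate,
#'   vote fraction, outcome).
#' @export
vote_contig_taxonomy <- function(tree, protein_taxids) {
  protein_taxids <- as.integer(protein_taxids)
  stopifnot(length(protein_taxids) > 0L)
  diag <- vector("list", length(canonical_ranks))
  for (k in seq_along(canonical_ranks)) {
    rank <- canonical_ranks[k]
    anc <- rank_ancestor(tree, protein_taxids, rank)
    voters <- !is.na(anc)
    outcome <- "no voters"
    cand <- NA_integer_
    frac <- NA_real_
    if (any(voters)) {
      tab <- table(anc[voters])
      top <- which(tab == max(tab))
      frac <- max(tab) / sum(voters)
      if (length(top) == 1L && frac >= 0.5) {
        cand <- as.integer(names(tab)[top])
        lower <- protein_taxids[!voters]
        if (length(lower) == 0L) {
          outcome <- "accepted"
        } else {
          consistent <- vapply(lower, function(t)
            is_ancestor(tree, cand, t), logical(1))
          outcome <- if (sum(consistent) * 2L > length(lower))
            "accepted" else "proviso failed"
        }
      } else {
        outcome <- if (frac >= 0.5) "tie" else "no majority"
      }
    }
    diag[[k]] <- tibble::tibble(rank = rank, candidate = cand,
                                fraction = frac, outcome = outcome)
    if (outcome == "accepted") {
      return(list(taxid = cand, rank = rank,
                  votes = dplyr::bind_rows(diag[seq_len(k)])))
    }
  }
  list(taxid = taxon_lca_all(tree, protein_taxids), rank = "lca",
       votes = dplyr::bind_rows(diag))
}

#' Contig-level taxonomy from protein classifications
#'
#' Applies [vote_contig_taxonomy()] per contig.
#'
#' @param protein_taxa Data frame with columns `contig`, `taxid` (one row
#'   per classified protein), e.g. the output of [classify_proteins()].
#' @param tree A [taxonomy] object.
#' @return Tibble `contig`, `taxid`, `rank`, `n_proteins`.
#' @export
assign_contig_taxonomy <- function(protein_taxa, tree) {
  protein_taxa <- tibble::as_tibble(protein_taxa)
  protein_taxa |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(
      res = list(vote_contig_taxonomy(tree, .data$taxid)),
      n_proteins = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      taxid = vapply(.data$res, `[[`, integer(1), "taxid"),
      rank = vapply(.data$res, `[[`, character(1), "rank")
    ) |>
    dplyr::select("contig", "taxid", "rank", "n_proteins")
}

#' Partition contigs into kingdom bins
#'
#' Each contig is keyed by the superkingdom ancestor of its assigned taxid
#' (Bacteria, Archaea, Eukaryota, ...); contigs whose assignment resolves
#' above the superkingdom level (e.g. the root) go to `"unclassified"`.
#'
#' @param contig_taxa Output of [assign_contig_taxonomy()] (columns `contig`,
#'   `taxid`).
#' @param tree A [taxonomy] object.
#' @return The input tibble with an added `kingdom` column.
#' @export
partition_kingdoms <- function(contig_taxa, tree) {
  contig_taxa <- tibble::as_tibble(contig_taxa)
  sk <- rank_ancestor(tree, contig_taxa$taxid, "superkingdom")
  kingdom <- ifelse(is.na(sk), "unclassified",
                    tree$nodes$name[unname(tree$index[as.character(sk)])])
  dplyr::mutate(contig_taxa, kingdom = kingdom)
}
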