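#' Read an assembly FASTA
#'
#' @param path FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] named by contig id (header text up
#'   to the first whitespace).
#' @export
read_assembly <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Resolve per-contig coverage
#'
#' Precedence: an explicit two-column TSV (`contig`, `coverage`), else
#' SPAdes-style `_cov_<x>` suffixes in the contig names, else an error.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (the assembly).
#' @param coverage Optional path to a coverage TSV (or a data frame).
#' @return Tibble `contig`, `coverage` covering every contig.
#' @export
resolve_coverage <- function(seqs, coverage = NULL) {
  ids <- names(seqs)
  if (!is.null(coverage)) {
    tbl <- if (is.data.frame(coverage)) tibble::as_tibble(coverage) else
      readr::read_tsv(coverage, col_types = readr::cols(
        contig = "c", coverage = "d"))
    missing <- setdiff(ids, tbl$contig)
    if (length(missing) > 0L) {
      stop("no coverage for ", length(missing), " contig(s), e.g. ",
           missing[1])
    }
    return(tibble::tibble(contig = ids,
                          coverage = tbl$coverage[match(ids, tbl$contig)]))
  }
  m <- regmatches(ids, regexpr("_cov_[0-9]+\\.?[0-9]*", ids))
  if (length(m) == length(ids)) {
    return(tibble::tibble(contig = ids,
                          coverage = as.numeric(sub("_cov_", "", m))))
  }
  stop("coverage unavailable: supply a coverage TSV or use SPAdes-style ",
       "'_cov_<x>' contig names")
}

#' Read protein homology hits
#' @param path Headered TSV `qseqid`, `contig`, `staxid`, `bitscore`.
#' @export
read_protein_hits <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    qseqid = "c", contig = "c", staxid = "i", bitscore = "d"))
}

#' Read a marker set (one id per line, header `marker_id`)
#' @param path Path to the TSV.
#' @export
read_marker_set <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))$marker_id
}

#' Read a binning ground truth table
#' @param path Headered TSV `contig`, `genome`, `length`, `misassembled`.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = "c", genome = "c", length = "d", misassembled = "i"))
}

#' Write per-bin FASTA files
#'
#' @param assignment Data frame `bin`, `contig`.
#' @param seqs Named [Biostrings::DNAStringSet].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_bin_fasta <- function(assignment, seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(assignment$contig, assignment$bin), function(ctgs) {
    ""
  }, character(1))
  for (b in unique(assignment$bin)) {
    ctgs <- assignment$contig[assignment$bin == b]
    p <- file.path(dir, paste0(b, ".fasta"))
    Biostrings::writeXStringSet(seqs[ctgs], p)
    paths[b] <- p
  }
  invisible(paths)
}
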