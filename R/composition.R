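#' Canonical k-mer keys
#'
#' All 4^k DNA words collapsed with their reverse complements; for odd k
#' (no palindromes) this yields 4^k / 2 keys, i.e. 512 at k = 5.
#'
#' @param k Word size (odd k recommended).
#' @return Character vector of canonical keys, lexicographically sorted.
#' @export
canonical_kmers <- function(k = 5) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  sort(unique(pmin(words, rc)))
}

#' Count canonical k-mers per contig
#'
#' Every length-k window consisting solely of A/C/G/T increments the
#' lexicographically smaller of the window and its reverse complement;
#' windows containing ambiguity codes are skipped. Contig strand therefore
#' does not affect the profile.
#'
#' @param seqs A [Biostrings::DNAStringSet], named character vector of
#'   sequences, or path to a FASTA file.
#' @param k Word size (default 5).
#' @return Integer matrix, contigs x canonical k-mers. Row sums equal the
#'   number of unambiguous windows per contig.
#' @export
count_kmers <- function(seqs, k = 5) {
  seqs <- as_dna(seqs)
  short <- Biostrings::width(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k,
            "; their counts are all zero")
  }
  raw <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  words <- colnames(raw)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  canon <- pmin(words, rc)
  keys <- sort(unique(canon))
  out <- matrix(0L, nrow = nrow(raw), ncol = length(keys),
                dimnames = list(names(seqs), keys))
  for (j in seq_along(words)) {
    out[, canon[j]] <- out[, canon[j]] + raw[, j]
  }
  out
}

as_dna <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) return(seqs)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    return(Biostrings::readDNAStringSet(seqs))
  }
  Biostrings::DNAStringSet(seqs)
}

#' Centered log-ratio normalisation of a count matrix
#'
#' Adds a pseudocount of 1 to every cell, converts rows to relative
#' frequencies, and applies the centered log-ratio transform (log frequency
#' minus the row mean of log frequencies). Output rows sum to zero and are
#' invariant to scaling all counts in a row.
#'
#' @param counts Non-negative count matrix (contigs x k-mers).
#' @return Real matrix of the same shape.
#' @export
clr_normalize <- function(counts) {
  stopifnot(nrow(counts) > 0L)
  x <- counts + 1
  lf <- log(x / rowSums(x))
  lf - rowMeans(lf)
}

#' Reduce a normalised composition matrix with PCA
#'
#' Principal components ordered by decreasing explained variance. Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive, making the output deterministic.
#'
#' @param x Real matrix (contigs x features), e.g. from [clr_normalize()].
#' @param dims Number of components to keep (default 50); capped at the
#'   matrix rank.
#' @return Score matrix (contigs x components) with attribute
#'   `explained_variance` (per-component variances) and `rotation`.
#' @export
pca_reduce <- function(x, dims = 50) {
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(dims, ncol(p$rotation)))
  rot <- p$rotation[, keep, drop = FALSE]
  scores <- p$x[, keep, drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    rot[which.max(abs(rot[, j])), j] < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip]
  scores[, flip] <- -scores[, flip]
  rownames(scores) <- rownames(x)
  attr(scores, "explained_variance") <- p$sdev[keep]^2
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- p$center
  scores
}

#' Embed composition coordinates in 2-D with Barnes-Hut t-SNE
#'
#' Wraps [Rtsne::Rtsne] single-threaded under a fixed seed so the embedding
#' is reproducible. t-SNE requires perplexity < (n - 1) / 3; for smaller
#' inputs the perplexity is lowered to floor((n - 1) / 3) with a warning.
#'
#' @param x Numeric matrix (contigs x dims), typically PCA scores; rownames
#'   are contig ids.
#' @param perplexity Effective neighbour count (default 30).
#' @param seed Integer seed; required, and recorded on the output.
#' @param theta Barnes-Hut accuracy/speed trade-off (0 = exact).
#' @param max_iter Gradient-descent iterations.
#' @return Tibble `contig`, `x`, `y` with attributes `perplexity` and
#'   `seed`.
#' @export
embed_tsne <- function(x, perplexity = 30, seed, theta = 0.5,
                       max_iter = 1000) {
  stopifnot(is.matrix(x), !missing(seed))
  n <- nrow(x)
  if (n < 4L) stop("t-SNE embedding requires at least 4 rows")
  if (perplexity > (n - 1) / 3) {
    perplexity <- floor((n - 1) / 3)
    warning("perplexity lowered to ", perplexity, " for n = ", n, " rows")
  }
  fit <- withr::with_seed(as.integer(seed),
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = theta,
                 max_iter = max_iter, pca = FALSE, check_duplicates = FALSE,
                 verbose = FALSE, num_threads = 1)
  )
  out <- tibble::tibble(
    contig = if (is.null(rownames(x))) as.character(seq_len(n)) else rownames(x),
    x = fit$Y[, 1], y = fit$Y[, 2]
  )
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Full composition stage: k-mer counts to PCA scores and t-SNE coordinates
#'
#' @inheritParams count_kmers
#' @inheritParams embed_tsne
#' @param dims PCA dimensions retained (default 50).
#' @return List with `pca` (score matrix) and `embedding` (tibble
#'   `contig`, `x`, `y`).
#' @export
compose_contigs <- function(seqs, k = 5, dims = 50, perplexity = 30, seed,
                            max_iter = 1000) {
  counts <- count_kmers(seqs, k = k)
  pca <- pca_reduce(clr_normalize(counts), dims = dims)
  list(pca = pca,
       embedding = embed_tsne(pca, perplexity = perplexity, seed = seed,
                              max_iter = max_iter))
}
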