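#' Recruitment stage configuration
#'
#' @param n_subsamples Number of jackknife subsamples (default 10; the
#'   confidence granularity is 100 / n_subsamples).
#' @param subsample_fraction Fraction of training rows per subsample
#'   (default 0.5), drawn stratified so every bin keeps at least one row.
#' @param confidence_min Confidence required to accept a prediction
#'   (default 100).
#' @param use_taxonomy Add binary taxon indicator columns to the feature
#'   matrix (default FALSE).
#' @param seed Seed for the subsample draws.
#' @export
recruit_config <- function(n_subsamples = 10, subsample_fraction = 0.5,
                           confidence_min = 100, use_taxonomy = FALSE,
                           seed = 1) {
  structure(
    list(n_subsamples = n_subsamples,
         subsample_fraction = subsample_fraction,
         confidence_min = confidence_min, use_taxonomy = use_taxonomy,
         seed = as.integer(seed)),
    class = "recruit_config"
  )
}

#' Build the classifier feature matrix
#'
#' Features are the PCA composition coordinates plus coverage, optionally
#' extended with a binary indicator column for every taxon observed at each
#' canonical rank among the supplied contigs (contigs with no node at a
#' rank encode as all zeros there).
#'
#' @param contigs Tibble with `contig`, `coverage` and, if indicators are
#'   wanted, `taxid`.
#' @param pca PCA score matrix with contig rownames.
#' @param tree Optional [taxonomy]; required for indicator columns.
#' @param use_taxonomy Add the indicator block (default FALSE).
#' @return Tibble: `contig` plus numeric feature columns.
#' @export
build_features <- function(contigs, pca, tree = NULL, use_taxonomy = FALSE) {
  contigs <- tibble::as_tibble(contigs)
  feat <- tibble::as_tibble(pca[contigs$contig, , drop = FALSE],
                            .name_repair = "minimal")
  names(feat) <- paste0("PC", seq_len(ncol(feat)))
  feat <- dplyr::bind_cols(tibble::tibble(contig = contigs$contig), feat,
                           tibble::tibble(coverage = contigs$coverage))
  if (use_taxonomy) {
    stopifnot(!is.null(tree), "taxid" %in% names(contigs))
    for (rank in canonical_ranks) {
      anc <- rank_ancestor(tree, contigs$taxid, rank)
      for (t in sort(unique(anc[!is.na(anc)]))) {
        feat[[paste0("tax_", rank, "_", t)]] <- as.numeric(!is.na(anc) & anc == t)
      }
    }
  }
  feat
}

train_tree <- function(train) {
  rpart::rpart(
    .bin ~ ., data = train, method = "class",
    control = rpart::rpart.control(minsplit = 2, cp = 0, xval = 0,
                                   maxcompete = 0, maxsurrogate = 0)
  )
}

#' Jackknife-confidence classification
#'
#' Trains `n_subsamples` decision trees, each on an independent stratified
#' 50% subsample of the training rows (every bin keeps at least one row),
#' and reports for each query the modal predicted bin and the percentage of
#' trees voting for it.
#'
#' @param train_x,query_x Feature tibbles (a `contig` id column is ignored
#'   if present).
#' @param train_y Bin labels for the training rows.
#' @param config A [recruit_config()].
#' @return Tibble `label`, `confidence` (one row per query row). Modal-label
#'   ties are broken alphabetically, which only affects predictions already
#'   below 100% confidence.
#' @export
jackknife_classify <- function(train_x, train_y, query_x,
                               config = recruit_config()) {
  drop_id <- function(x) x[, setdiff(names(x), "contig"), drop = FALSE]
  train_x <- drop_id(tibble::as_tibble(train_x))
  query_x <- drop_id(tibble::as_tibble(query_x))
  train_y <- factor(train_y)
  if (nlevels(train_y) < 2L) stop("jackknife classification needs >= 2 bins")
  if (any(table(train_y) < 2L)) stop("every bin needs >= 2 training rows")
  votes <- matrix(NA_character_, nrow(query_x), config$n_subsamples)
  idx_by_class <- split(seq_along(train_y), train_y)
  for (s in seq_len(config$n_subsamples)) {
    sel <- withr::with_seed(config$seed + s, {
      unlist(lapply(idx_by_class, function(ix) {
        sample(ix, max(1L, round(length(ix) * config$subsample_fraction)))
      }), use.names = FALSE)
    })
    fit <- train_tree(cbind(.bin = train_y[sel], train_x[sel, , drop = FALSE]))
    votes[, s] <- as.character(predict(fit, query_x, type = "class"))
  }
  res <- apply(votes, 1, function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    # sort() is stable; break count ties alphabetically for determinism
    top <- names(tab)[tab == max(tab)]
    c(label = sort(top)[1], conf = 100 * max(tab) / length(v))
  })
  tibble::tibble(label = unname(res["label", ]),
                 confidence = as.numeric(res["conf", ]))
}

#' Accept or reject a single recruitment prediction
#'
#' Accepted only at full jackknife confidence and only when none of the
#' contig's markers are already present in the target bin (which would add
#' marker contamination).
#'
#' @param confidence Jackknife confidence in percent.
#' @param contig_markers Marker ids on the candidate contig.
#' @param bin_markers Marker ids already present in the target bin.
#' @param confidence_min Required confidence (default 100).
#' @return List `accepted` (logical) and `reason` (`"none"`,
#'   `"low confidence"` or `"contamination"`).
#' @export
accept_prediction <- function(confidence, contig_markers, bin_markers,
                              confidence_min = 100) {
  if (confidence < confidence_min) {
    list(accepted = FALSE, reason = "low confidence")
  } else if (any(contig_markers %in% bin_markers)) {
    list(accepted = FALSE, reason = "contamination")
  } else {
    list(accepted = TRUE, reason = "none")
  }
}

#' Recruit unclustered contigs into accepted bins
#'
#' A decision-tree classifier is trained on the marker-containing contigs
#' of each bin. Rounds proceed over the unclustered marker-containing
#' contigs: predictions at full jackknife confidence that add no marker
#' contamination are accepted, join their bin and the training data, and
#' the classifier is retrained, until a round accepts nothing. A final pass
#' then assigns markerless contigs under the same confidence rule (they
#' never join the training data).
#'
#' @param assignment Binning assignment tibble (`bin`, `contig`, ...), e.g.
#'   from [cluster_contigs()].
#' @param unclustered Contig ids not in any bin.
#' @param features Feature tibble from [build_features()] covering both
#'   binned and unclustered contigs.
#' @param marker_hits Data frame `contig`, `marker_id`.
#' @param config A [recruit_config()].
#' @return List with `assignment` (input plus accepted recruits, flagged by
#'   `recruited`), `unclustered` (remaining ids) and `log`, a tibble
#'   `contig`, `bin`, `confidence`, `accepted`, `reason`, `round`
#'   recording every scored prediction.
#' @export
recruit_contigs <- function(assignment, unclustered, features, marker_hits,
                            config = recruit_config()) {
  assignment <- tibble::as_tibble(assignment)
  if (!"recruited" %in% names(assignment)) assignment$recruited <- FALSE
  log <- list()
  empty <- list(assignment = assignment, unclustered = unclustered,
                log = tibble::tibble(contig = character(), bin = character(),
                                     confidence = numeric(),
                                     accepted = logical(),
                                     reason = character(), round = integer()))
  if (length(unclustered) == 0L) return(empty)

  marker_contigs <- unique(marker_hits$contig)
  bin_of <- stats::setNames(assignment$bin, assignment$contig)
  markers_of <- split(marker_hits$marker_id, marker_hits$contig)
  bin_markers <- lapply(split(assignment$contig, assignment$bin), function(cs)
    unique(unlist(markers_of[cs], use.names = FALSE)))

  # training pool: marker-containing contigs of bins with >= 2 of them
  train_ids <- assignment$contig[assignment$contig %in% marker_contigs]
  tab <- table(bin_of[train_ids])
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L) {
    warning("recruitment skipped: fewer than 2 bins with >= 2 ",
            "marker-containing training contigs")
    return(empty)
  }
  train_ids <- train_ids[bin_of[train_ids] %in% usable]
  feat <- tibble::as_tibble(features)
  frow <- function(ids) feat[match(ids, feat$contig), , drop = FALSE]

  round <- 0L
  pool <- sort(unclustered)
  repeat {
    round <- round + 1L
    queries <- pool[pool %in% marker_contigs]
    if (length(queries) == 0L) break
    pred <- jackknife_classify(frow(train_ids), bin_of[train_ids],
                               frow(queries), config)
    accepted_any <- FALSE
    for (qi in seq_along(queries)) {
      ctg <- queries[qi]
      lab <- pred$label[qi]
      dec <- accept_prediction(pred$confidence[qi],
                               markers_of[[ctg]] %||% character(),
                               bin_markers[[lab]] %||% character(),
                               config$confidence_min)
      log[[length(log) + 1L]] <- tibble::tibble(
        contig = ctg, bin = lab, confidence = pred$confidence[qi],
        accepted = dec$accepted, reason = dec$reason, round = round)
      if (dec$accepted) {
        accepted_any <- TRUE
        bin_of[ctg] <- lab
        bin_markers[[lab]] <- union(bin_markers[[lab]], markers_of[[ctg]])
        train_ids <- c(train_ids, ctg)
        pool <- setdiff(pool, ctg)
      }
    }
    if (!accepted_any) break
  }

  # final pass: markerless contigs; accepted ones never join training
  queries <- pool[!(pool %in% marker_contigs)]
  if (length(queries) > 0L) {
    round <- round + 1L
    pred <- jackknife_classify(frow(train_ids), bin_of[train_ids],
                               frow(queries), config)
    for (qi in seq_along(queries)) {
      ctg <- queries[qi]
      dec <- accept_prediction(pred$confidence[qi], character(),
                               character(), config$confidence_min)
      log[[length(log) + 1L]] <- tibble::tibble(
        contig = ctg, bin = pred$label[qi], confidence = pred$confidence[qi],
        accepted = dec$accepted, reason = dec$reason, round = round)
      if (dec$accepted) {
        bin_of[ctg] <- pred$label[qi]
        pool <- setdiff(pool, ctg)
      }
    }
  }

  recruited <- setdiff(names(bin_of), assignment$contig)
  out <- dplyr::bind_rows(
    assignment,
    tibble::tibble(bin = unname(bin_of[recruited]), contig = recruited,
                   recruited = TRUE)
  )
  list(assignment = out, unclustered = pool,
       log = dplyr::bind_rows(log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
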