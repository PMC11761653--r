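#' Evaluation protocols
#'
#' Test-set stratification by Hamming distance of the 34-residue
#' binding-pocket signature to the training set, top-k accuracy with
#' multi-label ground truth for promiscuous domains, leave-one-substrate-out
#' splitting for zero-shot benchmarking, and the promiscuous-domain split.
#'
#' @name evaluation
NULL

#' Bucket specification for Hamming stratification
#'
#' @param thresholds nonnegative strictly increasing integers; default
#'   c(0, 3, 6, 9, 12), i.e. buckets B0+, B3+, B6+, B9+, B12+.
#' @export
bucket_spec <- function(thresholds = c(0L, 3L, 6L, 9L, 12L)) {
  stopifnot(all(thresholds >= 0), all(diff(thresholds) > 0))
  structure(list(thresholds = as.integer(thresholds)), class = "bucket_spec")
}

#' Stratify test records into Hamming buckets
#'
#' A test record belongs to bucket Bi+ iff the minimum Hamming distance of
#' its signature to every training signature is at least i; buckets are
#' nested and B0+ contains everything.
#'
#' @param test_sigs,train_sigs character vectors of 34-residue signatures.
#' @param spec a [bucket_spec()].
#' @return logical matrix, one row per test record, one column per bucket
#'   (named "B<i>+"), plus attribute `min_distance`.
#' @export
stratify_buckets <- function(test_sigs, train_sigs, spec = bucket_spec()) {
  if (!length(train_sigs)) stop("empty training set")
  mind <- vapply(test_sigs, function(s) {
    min(vapply(train_sigs, hamming, 0L, sigA = s))
  }, 0L, USE.NAMES = FALSE)
  m <- outer(mind, spec$thresholds, ">=")
  colnames(m) <- sprintf("B%d+", spec$thresholds)
  attr(m, "min_distance") <- mind
  m
}

#' Top-k accuracy over ranked prediction lists
#'
#' A record counts as a hit when any of its true substrates (promiscuous
#' records carry several) appears among the first k predictions.
#'
#' @param predictions list of character vectors, each the ranked substrate
#'   names for one record.
#' @param truth list of character vectors (or a character vector) of the true
#'   substrate(s) per record.
#' @param k integer.
#' @return fraction of records hit, in [0, 1].
#' @export
topk_accuracy <- function(predictions, truth, k) {
  if (!is.list(truth)) truth <- as.list(truth)
  stopifnot(length(predictions) == length(truth))
  if (any(lengths(truth) == 0L)) stop("record without truth label")
  hits <- mapply(function(p, t) any(t %in% utils::head(p, k)),
                 predictions, truth)
  mean(hits)
}

#' Leave-one-substrate-out split
#'
#' Removes every pair carrying the held-out substrate from the training set;
#' those pairs become the test set. The substrate itself stays in the
#' embedding-database library as a zero-shot target.
#'
#' @param pairs data.frame with columns adomain_id, substrate.
#' @param held_out substrate name present in `pairs`.
#' @return list(train, test) of pair data.frames.
#' @export
loso_split <- function(pairs, held_out) {
  pairs <- as.data.frame(pairs)
  if (!held_out %in% pairs$substrate) stop("substrate absent: ", held_out)
  sel <- pairs$substrate == held_out
  list(train = pairs[!sel, , drop = FALSE], test = pairs[sel, , drop = FALSE])
}

#' Promiscuous-domain split
#'
#' Sequences observed with more than one substrate are promiscuous. For each
#' promiscuous A-domain one randomly chosen pair goes to the training set and
#' the remaining n-1 pairs to the test set; all non-promiscuous pairs train.
#'
#' @param pairs data.frame with columns adomain_id, substrate.
#' @param seed integer; the split is deterministic given the seed.
#' @return list(train, test).
#' @export
promiscuous_split <- function(pairs, seed = 1L) {
  pairs <- as.data.frame(pairs)
  n_by_id <- table(pairs$adomain_id)
  prom <- names(n_by_id)[n_by_id > 1L]
  withr::with_seed(as.integer(seed), {
    test_rows <- logical(nrow(pairs))
    for (id in prom) {
      rows <- which(pairs$adomain_id == id)
      keep <- rows[sample.int(length(rows), 1L)]
      test_rows[setdiff(rows, keep)] <- TRUE
    }
  })
  list(train = pairs[!test_rows, , drop = FALSE],
       test = pairs[test_rows, , drop = FALSE])
}

#' Grouped split
#'
#' Generic train-on-group-A / test-on-group-B split driven by a metadata
#' column (e.g. taxonomic origin).
#'
#' @param pairs data.frame including a metadata column.
#' @param group_col column name.
#' @param train_groups,test_groups values of that column.
#' @return list(train, test).
#' @export
grouped_split <- function(pairs, group_col, train_groups, test_groups) {
  pairs <- as.data.frame(pairs)
  stopifnot(group_col %in% names(pairs))
  list(train = pairs[pairs[[group_col]] %in% train_groups, , drop = FALSE],
       test = pairs[pairs[[group_col]] %in% test_groups, , drop = FALSE])
}

#' Repeated random train/test splits
#'
#' Seeded shuffle splits of unique A-domain sequences (so a promiscuous
#' domain's pairs never straddle the boundary), 80/20 by default, repeated
#' `n_splits` times.
#'
#' @param pairs data.frame with columns adomain_id, substrate.
#' @param n_splits number of repeats (default 12).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer.
#' @return list of list(train, test).
#' @export
random_splits <- function(pairs, n_splits = 12L, train_frac = 0.8, seed = 1L) {
  pairs <- as.data.frame(pairs)
  ids <- unique(pairs$adomain_id)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_splits), function(i) {
      tr <- sample(ids, ceiling(train_frac * length(ids)))
      list(train = pairs[pairs$adomain_id %in% tr, , drop = FALSE],
           test = pairs[!pairs$adomain_id %in% tr, , drop = FALSE])
    })
  })
}

#' Evaluate a trained model on a labelled test set
#'
#' @param model a `specificity_model`.
#' @param test_pairs data.frame(adomain_id, substrate); promiscuous domains
#'   may repeat.
#' @param features named list of P x D matrices covering the test ids.
#' @param signatures optional named character vector of 34-residue signatures
#'   (test ids) and `train_signatures` for bucket stratification.
#' @param train_signatures see `signatures`.
#' @param k_values ks at which accuracy is reported.
#' @param spec a [bucket_spec()].
#' @param search passed to [predict_topk()].
#' @param fingerprint_db target-fingerprint matrix (rows named by substrate),
#'   required when `search = "fingerprint"`.
#' @return an `eval_report` list: overall and per-bucket top-k accuracies and
#'   bucket counts.
#' @export
evaluate_model <- function(model, test_pairs, features,
                           signatures = NULL, train_signatures = NULL,
                           k_values = c(1L, 3L, 5L), spec = bucket_spec(),
                           search = "latent", fingerprint_db = NULL) {
  test_pairs <- as.data.frame(test_pairs)
  ids <- unique(test_pairs$adomain_id)
  truth <- lapply(ids, function(i) test_pairs$substrate[test_pairs$adomain_id == i])
  names(truth) <- ids
  kmax <- max(k_values)
  fp_db <- if (identical(search, "fingerprint")) {
    if (is.null(fingerprint_db)) stop("fingerprint-space search needs fingerprint_db")
    fingerprint_db
  } else NULL
  preds <- lapply(ids, function(i) {
    predict_topk(features[[i]], model, k = kmax, search = search,
                 db = fp_db)$substrate
  })
  overall <- vapply(k_values, function(k) topk_accuracy(preds, truth, k), 0)
  names(overall) <- sprintf("top%d", k_values)
  rep <- list(overall = overall, n = length(ids))
  if (!is.null(signatures) && !is.null(train_signatures)) {
    bm <- stratify_buckets(signatures[ids], train_signatures, spec)
    per_bucket <- lapply(colnames(bm), function(b) {
      sel <- bm[, b]
      if (!any(sel)) return(setNames(rep(NA_real_, length(k_values)),
                                     names(overall)))
      vapply(k_values, function(k) topk_accuracy(preds[sel], truth[sel], k), 0) |>
        setNames(sprintf("top%d", k_values))
    })
    names(per_bucket) <- colnames(bm)
    rep$per_bucket <- per_bucket
    rep$bucket_counts <- colSums(bm)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d records>\n  overall: %s\n", x$n,
              paste(sprintf("%s=%.3f", names(x$overall), x$overall),
                    collapse = " ")))
  if (!is.null(x$bucket_counts)) {
    cat("  bucket counts:",
        paste(sprintf("%s=%d", names(x$bucket_counts), x$bucket_counts),
              collapse = " "), "\n")
  }
  invisible(x)
}
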