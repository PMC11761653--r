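#' The fingerprint-regression specificity model
#'
#' Two networks are trained jointly. The *fingerprint predictor* maps the
#' 10 x D binding-pocket residue features of an A-domain to the 296-entry
#' substrate fingerprint, minimizing batch-mean cosine distance. The
#' *classifier head* (296 -> 296 identity-initialized linear, ReLU, 296 -> L)
#' is trained with cross-entropy to recover the substrate label from both the
#' predicted and the target fingerprint; its gradients never flow back into
#' the predictor (stop-gradient), so it is updated twice per predictor step.
#' The ReLU hidden layer of the head is the latent substrate embedding used
#' for nearest-neighbour search, which makes zero-shot retrieval possible:
#' any substrate with a SMILES can be embedded into the database without
#' retraining.
#'
#' @name specificity_model
NULL

#' Cosine distance between two vectors
#'
#' @param u,v equal-length numeric vectors, each with at least one nonzero
#'   entry.
#' @return 1 - cos(u, v), in [0, 2].
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero vector")
  1 - sum(u * v) / (nu * nv)
}

#' Training configuration
#'
#' Defaults: 80 epochs, batch 128,
#' learning rate 1e-4 for both networks, exponential decay x0.8 every ten
#' epochs, decoupled weight decay.
#'
#' @param epochs,batch_size,lr,lr_decay,decay_every,weight_decay,head_lr
#'   optimizer settings.
#' @param mode "latent" (full model), or "direct" (ablation: the trunk
#'   classifies labels directly, final width L, no head).
#' @param seed integer seed governing all randomness of a training run.
#' @return a list of class `model_config`.
#' @export
model_config <- function(epochs = 80L, batch_size = 128L, lr = 1e-4,
                         lr_decay = 0.8, decay_every = 10L,
                         weight_decay = 0.01, head_lr = 1e-4,
                         mode = c("latent", "direct"), seed = 1L) {
  mode <- match.arg(mode)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 weight_decay = weight_decay, head_lr = head_lr,
                 mode = mode, seed = as.integer(seed)),
            class = "model_config")
}

predictor_ops <- function(D, P, out = 296L) {
  list(nn_linear(D, 480L), nn_elu(), nn_layernorm(480L),
       nn_linear(480L, 240L), nn_elu(), nn_layernorm(240L),
       nn_flatten(P),
       nn_linear(P * 240L, 240L), nn_elu(), nn_layernorm(240L),
       nn_linear(240L, 240L), nn_elu(), nn_layernorm(240L),
       nn_linear(240L, out))
}

head_ops <- function(L) {
  list(nn_linear_identity(296L), nn_relu(), nn_linear(296L, L))
}

stack_features <- function(features) {
  P <- nrow(features[[1]]); D <- ncol(features[[1]])
  ok <- vapply(features, function(f) nrow(f) == P && ncol(f) == D, TRUE)
  if (!all(ok)) stop("configuration error: mixed feature dimensions")
  list(X = do.call(rbind, features), P = P, D = D)
}

#' Train the specificity model
#'
#' @param pairs data.frame with columns `adomain_id` and `substrate`; one row
#'   per (A-domain, observed substrate) pair. Promiscuous domains contribute
#'   several rows.
#' @param features named list, one P x D feature matrix per `adomain_id`
#'   (from [featurize_residues()] or [featurize_onehot()]).
#' @param library a `substrate_library` containing (at least) every substrate
#'   named in `pairs`; its fingerprints are the regression targets, and all
#'   of its substrates enter the embedding database (substrates absent from
#'   the training labels become zero-shot candidates).
#' @param config a [model_config()].
#' @return an object of class `specificity_model`.
#' @export
train_specificity_model <- function(pairs, features, library,
                                    config = model_config()) {
  stopifnot(inherits(library, "substrate_library"))
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) stop("empty training dataset")
  stopifnot(all(c("adomain_id", "substrate") %in% names(pairs)))
  missing_feat <- setdiff(pairs$adomain_id, names(features))
  if (length(missing_feat)) stop("features missing for: ",
                                 paste(utils::head(missing_feat, 3), collapse = ", "))
  fps <- fingerprint_matrix(library)
  missing_sub <- setdiff(pairs$substrate, rownames(fps))
  if (length(missing_sub)) stop("substrates absent from library: ",
                                paste(utils::head(missing_sub, 3), collapse = ", "))
  sf <- stack_features(features[pairs$adomain_id])
  labels_chr <- sort(unique(pairs$substrate))
  L <- length(labels_chr)
  y_lab <- match(pairs$substrate, labels_chr)
  Y <- fps[pairs$substrate, , drop = FALSE]
  N <- nrow(pairs); P <- sf$P; D <- sf$D
  direct <- config$mode == "direct"

  withr::with_seed(config$seed, {
    pred <- predictor_ops(D, P, out = if (direct) L else 296L)
    head <- if (direct) NULL else head_ops(L)
    popt <- adamw_init(pred, lr = config$lr, weight_decay = config$weight_decay)
    hopt <- if (direct) NULL else
      adamw_init(head, lr = config$head_lr, weight_decay = config$weight_decay)
    counters <- c(predictor_steps = 0L, head_steps = 0L)
    epoch_loss <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr_now <- config$lr * config$lr_decay^((epoch - 1) %/% config$decay_every)
      ord <- sample.int(N)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      bl <- 0
      for (bi in batches) {
        rows <- as.vector(t(outer(bi, seq_len(P), function(i, p) (i - 1L) * P + p)))
        xb <- sf$X[rows, , drop = FALSE]
        fw <- nn_forward(pred, xb, cache = TRUE)
        if (direct) {
          ls <- ce_loss(fw$out, y_lab[bi])
        } else {
          ls <- cosine_loss(fw$out, Y[bi, , drop = FALSE])
        }
        bw <- nn_backward(pred, fw$caches, ls$grad)
        st <- adamw_step(pred, bw$grads, popt, lr = lr_now)
        pred <- st$ops; popt <- st$opt
        counters["predictor_steps"] <- counters["predictor_steps"] + 1L
        bl <- bl + ls$loss * length(bi)
        if (!direct) {
          # head update on the predicted fingerprints (gradient stopped at
          # the predictor boundary), then on the target fingerprints
          for (hin in list(fw$out, Y[bi, , drop = FALSE])) {
            hfw <- nn_forward(head, hin, cache = TRUE)
            hls <- ce_loss(hfw$out, y_lab[bi])
            hbw <- nn_backward(head, hfw$caches, hls$grad)
            hst <- adamw_step(head, hbw$grads, hopt, lr = lr_now)
            head <- hst$ops; hopt <- hst$opt
            counters["head_steps"] <- counters["head_steps"] + 1L
          }
        }
      }
      epoch_loss[epoch] <- bl / N
    }
  })

  lib_file <- tempfile()
  utils::write.table(fps, lib_file, sep = "\t")
  lib_hash <- unname(tools::md5sum(lib_file))
  unlink(lib_file)
  model <- structure(list(
    predictor = pred, head = head, labels = labels_chr,
    P = P, D = D, mode = config$mode, config = config, seed = config$seed,
    counters = counters, epoch_loss = epoch_loss,
    db = NULL, library_names = library$records$name,
    library_hash = lib_hash), class = "specificity_model")
  if (!direct) model$db <- build_embedding_db(library, model)
  model
}

#' @export
print.specificity_model <- function(x, ...) {
  cat(sprintf("<specificity_model: mode=%s, %d labels, features %dx%d, %d predictor steps>\n",
              x$mode, length(x$labels), x$P, x$D, x$counters["predictor_steps"]))
  invisible(x)
}

predict_fingerprint <- function(model, features) {
  stopifnot(nrow(features) == model$P, ncol(features) == model$D)
  drop(nn_forward(model$predictor, features))
}

#' Embed a substrate fingerprint into the latent space
#'
#' The rectified output of the head's first (identity-initialized) layer.
#' Entries are nonnegative by construction.
#'
#' @param fingerprint a 296-entry vector.
#' @param model a trained `specificity_model` (or a bare head op list).
#' @return a nonnegative 296-entry latent vector.
#' @export
embed_substrate <- function(fingerprint, model) {
  head <- if (inherits(model, "specificity_model")) model$head else model
  if (is.null(head)) stop("model has no classifier head (direct mode)")
  if (length(fingerprint) != 296L) stop("fingerprint must have length 296")
  h <- drop(fingerprint %*% head[[1]]$W) + head[[1]]$b
  pmax(h, 0)
}

#' Build the latent substrate-embedding database
#'
#' One latent vector per library substrate, computed from its *target*
#' fingerprint; substrates never seen in training are embedded the same way,
#' which is what enables zero-shot retrieval.
#'
#' @param library a `substrate_library`.
#' @param model a trained `specificity_model`.
#' @return numeric matrix, one named row per substrate.
#' @export
build_embedding_db <- function(library, model) {
  fps <- fingerprint_matrix(library)
  if (nrow(fps) == 0L) stop("empty substrate library")
  t(apply(fps, 1, embed_substrate, model = model))
}

#' Top-k nearest substrates for an A-domain
#'
#' Runs the fingerprint predictor on the features, embeds the predicted
#' fingerprint through the head, and ranks all database substrates by cosine
#' distance in latent space (or directly in fingerprint space for the
#' head-ablation search). Ties break lexicographically by substrate name.
#'
#' @param features P x D feature matrix of the query A-domain.
#' @param model a trained `specificity_model`.
#' @param k number of neighbours to return (>= 1).
#' @param search "latent" (default) or "fingerprint" (ablation: nearest
#'   search on raw fingerprints, bypassing the head).
#' @param db optional database matrix overriding `model$db` (for
#'   fingerprint-space search the target fingerprints themselves are used).
#' @return data.frame with columns rank, substrate, distance.
#' @export
predict_topk <- function(features, model, k = 3L,
                         search = c("latent", "fingerprint"), db = NULL) {
  search <- match.arg(search)
  if (k < 1L) stop("k must be >= 1")
  if (model$mode == "direct") {
    logits <- predict_fingerprint(model, features)
    ord <- order(-logits, model$labels)
    kk <- min(k, length(logits))
    return(data.frame(rank = seq_len(kk), substrate = model$labels[ord[seq_len(kk)]],
                      distance = -logits[ord[seq_len(kk)]],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  pred_fp <- predict_fingerprint(model, features)
  if (search == "latent") {
    if (is.null(db)) db <- model$db
    query <- embed_substrate(pred_fp, model)
  } else {
    if (is.null(db)) stop("fingerprint-space search needs a fingerprint db ",
                          "(pass db = fingerprint_matrix(library))")
    query <- pred_fp
  }
  if (is.null(db) || nrow(db) == 0L) stop("empty embedding database")
  d <- apply(db, 1, function(r) cosine_distance(query, r))
  ord <- order(d, rownames(db))
  kk <- min(k, nrow(db))
  data.frame(rank = seq_len(kk), substrate = rownames(db)[ord[seq_len(kk)]],
             distance = unname(d[ord[seq_len(kk)]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate the substructures driving a prediction
#'
#' Reports the binary fingerprint positions predicted above a threshold, the
#' substructure each position denotes (MACCS SMARTS pattern where the
#' OpenBabel definition file is available, otherwise a generic label; Morgan
#' positions are hashed circular-environment buckets), and whether the given
#' substrate actually sets that bit. The charge entry is returned separately
#' as an attribute.
#'
#' @param predicted_fp 296-entry predicted fingerprint.
#' @param substrate a `substrate_library` row name with the library, or a
#'   SMILES string, or a 296-entry target fingerprint.
#' @param threshold activation threshold in (0, 1).
#' @return data.frame with columns index, description, present; attribute
#'   `predicted_charge` carries entry 296.
#' @export
attribute_substructures <- function(predicted_fp, substrate, threshold = 0.5) {
  stopifnot(length(predicted_fp) == 296L, threshold > 0, threshold < 1)
  target <- if (is.numeric(substrate)) substrate else compute_fingerprint(substrate)
  idx <- which(predicted_fp[1:295] >= threshold)
  desc <- vapply(idx, function(i) {
    if (i <= FP_MACCS_LEN) maccs_description(i)
    else sprintf("Morgan radius-2 environment bucket %d", i - FP_MACCS_LEN)
  }, "")
  out <- data.frame(index = idx, description = desc,
                    present = target[idx] >= 0.5,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "predicted_charge") <- predicted_fp[296L]
  out
}

maccs_env <- new.env(parent = emptyenv())

maccs_description <- function(i) {
  if (is.null(maccs_env$tbl)) {
    tbl <- rep(NA_character_, FP_MACCS_LEN)
    ob <- Sys.which("obabel")
    if (nzchar(ob)) {
      root <- file.path(dirname(dirname(ob)), "share", "openbabel")
      f <- list.files(root, pattern = "^MACCS\\.txt$", recursive = TRUE,
                      full.names = TRUE)
      if (length(f)) {
        ln <- readLines(f[1], warn = FALSE)
        ln <- ln[!grepl("^\\s*(#|$)", ln)]
        parts <- strsplit(trimws(ln), "\\s+")
        for (p in parts) {
          j <- suppressWarnings(as.integer(p[length(p)]))
          if (!is.na(j) && j >= 1 && j <= FP_MACCS_LEN) tbl[j] <- p[1]
        }
      }
    }
    maccs_env$tbl <- tbl
  }
  d <- maccs_env$tbl[i]
  if (is.na(d)) sprintf("MACCS key %d", i) else sprintf("MACCS key %d: %s", i, d)
}

#' Save / load a trained model
#'
#' The archive bundles parameters, configuration, the substrate-name list and
#' the training seed.
#'
#' @param model a `specificity_model`.
#' @param path file path (.rds archive).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "specificity_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "specificity_model"))
  m
}
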