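test_that("cosine distance covers parallel, orthogonal and antiparallel cases", {
  u <- c(1, 2, 3)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(u, -u), 2)
  expect_error(cosine_distance(u, c(0, 0, 0)), "zero vector")
  expect_error(cosine_distance(u, c(1, 2)), "mismatch")
})

test_that("the classifier head starts from the identity map", {
  p <- fx_small()
  m0 <- train_specificity_model(p$ds$pairs, p$features, p$library,
                                model_config(epochs = 0L, seed = 1))
  expect_equal(m0$counters[["predictor_steps"]], 0L)
  expect_identical(m0$head[[1]]$W, diag(296))
  fp <- fingerprint_matrix(p$library)[1, ]
  emb <- embed_substrate(fp, m0)
  expect_equal(emb, pmax(fp, 0)) # identity + zero bias on the fresh head
  expect_true(all(emb >= 0))
})

test_that("the head is updated twice per predictor step", {
  m <- fx_small_model(epochs = 3L)
  expect_equal(m$counters[["head_steps"]],
               2L * m$counters[["predictor_steps"]])
  expect_gt(m$counters[["predictor_steps"]], 0L)
})

test_that("training is reproducible under a fixed seed", {
  p <- fx_small()
  cfg <- model_config(epochs = 2L, seed = 99L)
  m1 <- train_specificity_model(p$ds$pairs, p$features, p$library, cfg)
  m2 <- train_specificity_model(p$ds$pairs, p$features, p$library, cfg)
  expect_identical(m1$predictor[[1]]$W, m2$predictor[[1]]$W)
  expect_identical(m1$epoch_loss, m2$epoch_loss)
  expect_identical(m1$db, m2$db)
})

test_that("mixed feature dimensions and empty datasets are configuration errors", {
  p <- fx_small()
  bad <- p$features
  bad[[1]] <- bad[[1]][, 1:10]
  expect_error(train_specificity_model(p$ds$pairs, bad, p$library,
                                       model_config(epochs = 1L)),
               "mixed feature dimensions")
  expect_error(train_specificity_model(p$ds$pairs[0, ], p$features,
                                       p$library),
               "empty")
})

test_that("the embedding database has one nonnegative 296-entry row per substrate", {
  p <- fx_small()
  m <- fx_small_model()
  db <- m$db
  expect_equal(nrow(db), nrow(p$library$records))
  expect_equal(ncol(db), 296L)
  expect_true(all(db >= 0))
  # a novel substrate enters the database without retraining
  mono <- default_monomers()
  bigger <- substrate_library(rbind(
    p$library$records[, c("name", "smiles")],
    mono[mono$name == "tryptophan", c("name", "smiles")]))
  db2 <- build_embedding_db(bigger, m)
  expect_equal(nrow(db2), nrow(db) + 1L)
  expect_true("tryptophan" %in% rownames(db2))
})

test_that("top-k retrieval equals the exhaustive cosine sort", {
  p <- fx_small()
  m <- fx_small_model()
  id <- p$ds$pairs$adomain_id[1]
  res <- predict_topk(p$features[[id]], m, k = nrow(m$db))
  # oracle: recompute every distance and sort with the same tie-break
  pf <- hybridminer:::predict_fingerprint(m, p$features[[id]])
  q <- embed_substrate(pf, m)
  d <- apply(m$db, 1, function(r) cosine_distance(q, r))
  ord <- order(d, rownames(m$db))
  expect_equal(res$substrate, rownames(m$db)[ord])
  expect_equal(res$distance, unname(d[ord]))
  # k truncation
  expect_equal(nrow(predict_topk(p$features[[id]], m, k = 3L)), 3L)
  expect_equal(nrow(predict_topk(p$features[[id]], m, k = 100L)), nrow(m$db))
  expect_error(predict_topk(p$features[[id]], m, k = 0L), "k must be")
})

test_that("a query latent equal to a database entry ranks first at distance zero", {
  m <- fx_small_model()
  db <- m$db
  q <- db[2, ]
  d <- apply(db, 1, function(r) cosine_distance(q, r))
  ord <- order(d, rownames(db))
  expect_equal(rownames(db)[ord][1], rownames(db)[2])
  expect_equal(min(d), 0)
})

test_that("direct-classification ablation ranks labels without a head", {
  m <- fx_small_model(mode = "direct")
  p <- fx_small()
  expect_null(m$head)
  id <- p$ds$pairs$adomain_id[1]
  res <- predict_topk(p$features[[id]], m, k = 2L)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$substrate %in% m$labels))
})

test_that("substructure attribution annotates predicted bits", {
  p <- fx_small()
  gly_fp <- compute_fingerprint("NCC(=O)O")
  expect_equal(nrow(attribute_substructures(numeric(296), "NCC(=O)O")), 0L)
  # a prediction activating exactly one MACCS bit that glycine sets
  onbit <- which(gly_fp[1:167] == 1)[1]
  pred <- numeric(296); pred[onbit] <- 0.9
  att <- attribute_substructures(pred, gly_fp, threshold = 0.5)
  expect_equal(att$index, onbit)
  expect_true(att$present)
  expect_match(att$description, "MACCS")
  # indices stay within the binary segment
  pred2 <- rep(0.9, 296)
  att2 <- attribute_substructures(pred2, gly_fp, threshold = 0.5)
  expect_true(all(att2$index >= 1 & att2$index <= 295))
  expect_equal(attr(att2, "predicted_charge"), 0.9)
})

test_that("models survive a save/load round trip", {
  m <- fx_small_model()
  p <- fx_small()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  id <- p$ds$pairs$adomain_id[1]
  expect_identical(predict_topk(p$features[[id]], m, k = 3L),
                   predict_topk(p$features[[id]], m2, k = 3L))
})

test_that("latent search handles promiscuous domains at least as well as fingerprint search", {
  # each sequence maps to two chemically dissimilar substrates; the database
  # is larger than the label set, so midpoint predictions meet distractors
  # in fingerprint space. Asserted on the mean true-substrate rank averaged
  # over three seeded runs.
  mono <- default_monomers()
  amino <- mono[mono$class == "amino" & mono$enzymes == "",
                c("name", "smiles")]
  lib_full <- substrate_library(amino)
  fps <- fingerprint_matrix(lib_full)
  pairing <- c(glycine = "tryptophan", tryptophan = "glycine",
               alanine = "tyrosine", tyrosine = "alanine",
               serine = "phenylalanine", phenylalanine = "serine")
  ranks <- lapply(c(2L, 5L, 8L), function(seed) {
    ds <- make_adomain_dataset(planted_spec(
      n_substrates = 6L, seqs_per_substrate = 10L,
      substrates = names(pairing), seed = seed))
    pr <- rbind(ds$pairs,
                data.frame(adomain_id = ds$pairs$adomain_id,
                           substrate = unname(pairing[ds$pairs$substrate])))
    ft <- featurize_sequences(ds$sequences, backend = "onehot")$features
    sp <- promiscuous_split(pr, seed = seed)
    m <- train_specificity_model(sp$train, ft, lib_full,
                                 model_config(epochs = 40L,
                                              seed = seed + 100L))
    ids <- unique(sp$test$adomain_id)
    rank_of_truth <- function(i, search, db = NULL) {
      pk <- predict_topk(ft[[i]], m, k = nrow(fps), search = search,
                         db = db)
      min(match(pr$substrate[pr$adomain_id == i], pk$substrate))
    }
    c(latent = mean(vapply(ids, rank_of_truth, 0, search = "latent")),
      fingerprint = mean(vapply(ids, rank_of_truth, 0,
                                search = "fingerprint", db = fps)))
  })
  mean_lat <- mean(vapply(ranks, `[[`, 0, "latent"))
  mean_fp <- mean(vapply(ranks, `[[`, 0, "fingerprint"))
  expect_gte(mean_fp, mean_lat)
})
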