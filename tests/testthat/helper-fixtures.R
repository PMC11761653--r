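# Shared fixtures, computed lazily and cached for the whole test run.
# Heavy objects (trained models, toy genomes) are built once here so that
# individual test files stay fast.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# noiseless planted dataset under the study conditions: 8 substrates x 40
# sequences, one-hot signature featurization
fx_planted <- function() fx_get("planted", function() {
  ds <- make_adomain_dataset(planted_spec(seed = 7))
  ft <- featurize_sequences(ds$sequences, backend = "onehot")
  mono <- default_monomers()
  lib <- substrate_library(
    mono[mono$name %in% unique(ds$pairs$substrate), c("name", "smiles")])
  list(ds = ds, features = ft$features, signatures = ft$signatures,
       library = lib)
})

# full-length training run on the planted dataset
fx_model <- function() fx_get("model", function() {
  p <- fx_planted()
  train_specificity_model(p$ds$pairs, p$features, p$library,
                          model_config(seed = 11))
})

# small dataset + short training for structural / protocol checks
fx_small <- function() fx_get("small", function() {
  ds <- make_adomain_dataset(planted_spec(n_substrates = 4L,
                                          seqs_per_substrate = 8L, seed = 3))
  ft <- featurize_sequences(ds$sequences, backend = "onehot")
  mono <- default_monomers()
  lib <- substrate_library(
    mono[mono$name %in% unique(ds$pairs$substrate), c("name", "smiles")])
  list(ds = ds, features = ft$features, signatures = ft$signatures,
       library = lib)
})

fx_small_model <- function(epochs = 3L, seed = 5L, mode = "latent") {
  key <- sprintf("small_model_%d_%d_%s", epochs, seed, mode)
  p <- fx_small()
  fx_get(key, function() {
    train_specificity_model(p$ds$pairs, p$features, p$library,
                            model_config(epochs = epochs, seed = seed,
                                         mode = mode))
  })
}

# codes in which phenylalanine is a one-residue neighbour of leucine:
# phenylalanine is leucine's nearest fingerprint neighbour in the bundled
# library, so the held-out substrate has both a chemical and a
# binding-pocket near-twin
fx_loso_codes <- function() fx_get("loso_codes", function() {
  codes <- make_adomain_dataset(planted_spec(seed = 7))$codes
  ch <- strsplit(codes[["leucine"]], "")[[1]]
  ch[4] <- if (ch[4] == "A") "G" else "A"
  codes[["phenylalanine"]] <- paste(ch, collapse = "")
  stopifnot(!anyDuplicated(codes))
  codes
})

fx_toy_genome <- function() fx_get("toy_genome", function() {
  make_toy_genome(toy_bgc_spec(codes = fx_planted()$ds$codes, seed = 7),
                  dir = file.path(tempdir(), "toy_genome_fx"))
})

# brute-force simple-path oracle used against the assembly-line enumerator
oracle_paths_to_sink <- function(g, sink, min_len) {
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      vertices = g$gene_ids)
  out <- list()
  for (v in g$gene_ids) {
    if (v == sink) {
      if (min_len <= 1L) out <- c(out, list(sink))
      next
    }
    ap <- igraph::all_simple_paths(ig, from = v, to = sink, mode = "out")
    for (p in ap) {
      nm <- igraph::as_ids(p)
      if (length(nm) >= min_len) out <- c(out, list(nm))
    }
  }
  keys <- vapply(out, paste, "", collapse = "\r")
  out <- out[!duplicated(keys)]
  out[order(lengths(out), vapply(out, paste, "", collapse = "\r"))]
}

# naive injective label-preserving subgraph matcher (independent oracle)
oracle_subgraph_match <- function(pattern, target) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  adj <- function(g, n) {
    m <- matrix(0L, n, n)
    if (nrow(g$bonds)) {
      m[cbind(g$bonds$from, g$bonds$to)] <- g$bonds$order
      m[cbind(g$bonds$to, g$bonds$from)] <- g$bonds$order
    }
    m
  }
  ap <- adj(pattern, np); at <- adj(target, nt)
  res <- list()
  rec <- function(assign) {
    d <- length(assign) + 1L
    if (d > np) {
      res[[length(res) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (t in seq_len(nt)) {
      if (t %in% assign) next
      if (target$atoms$elem[t] != pattern$atoms$elem[d]) next
      ok <- TRUE
      for (j in seq_len(d - 1L)) {
        if (ap[d, j] > 0L && at[t, assign[j]] != ap[d, j]) { ok <- FALSE; break }
      }
      if (ok) rec(c(assign, t))
    }
    invisible(NULL)
  }
  rec(integer(0))
  keys <- vapply(res, function(m) paste(sort(m), collapse = ","), "")
  res[!duplicated(keys)]
}

make_gene <- function(id, domains, strand = "+", start = 0L, end = 100L) {
  bgc_gene(id, contig = "c", strand = strand, start = start, end = end,
           domains = domains)
}
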