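#' Synthetic A-domain training data
#'
#' Generates sequence/substrate pairs with a planted specificity signal: each
#' substrate is assigned a distinct 10-residue binding-pocket code, written
#' into the Stachelhaus positions of the reference scaffold; all other
#' positions receive seeded random point mutations. This emulates the
#' statistical structure the specificity model assumes (binding-pocket
#' residues determine specificity) without any real sequence diversity, so
#' passing tests demonstrate signal recovery, not performance on natural
#' A-domains.
#'
#' @param n_substrates number of substrates with planted codes.
#' @param seqs_per_substrate sequences generated per substrate.
#' @param substrates optional character vector of substrate names (defaults
#'   to the first `n_substrates` amino acids of the bundled monomer table).
#' @param promiscuity fraction of sequences that also carry a second,
#'   randomly chosen substrate label.
#' @param label_noise fraction of pairs whose label is replaced by a random
#'   other substrate.
#' @param mutation_rate per-residue substitution probability outside the
#'   planted code positions (default 0.1).
#' @param seed integer; the generator is a pure function of spec and seed.
#' @return object of class `planted_spec`.
#' @export
planted_spec <- function(n_substrates = 8L, seqs_per_substrate = 40L,
                         substrates = NULL, promiscuity = 0,
                         label_noise = 0, mutation_rate = 0.1, seed = 1L) {
  stopifnot(promiscuity >= 0, promiscuity <= 1, label_noise >= 0,
            label_noise <= 1, mutation_rate >= 0, mutation_rate <= 1)
  structure(list(n_substrates = as.integer(n_substrates),
                 seqs_per_substrate = as.integer(seqs_per_substrate),
                 substrates = substrates, promiscuity = promiscuity,
                 label_noise = label_noise, mutation_rate = mutation_rate,
                 seed = as.integer(seed)), class = "planted_spec")
}

#' Bundled monomer table
#'
#' The small monomer library shipped with the package: proteinogenic amino
#' acids, a few hydroxy acids, ketide extender units, and two conditional
#' monomers gated on tailoring enzymes.
#'
#' @return data.frame with columns name, smiles, class, attach, enzymes.
#' @export
default_monomers <- function() {
  utils::read.delim(system.file("extdata", "monomers.tsv",
                                package = "hybridminer", mustWork = TRUE),
                    stringsAsFactors = FALSE, na.strings = NULL)
}

#' @rdname planted_spec
#' @param spec a `planted_spec`.
#' @param ref a `reference_alignment` scaffold.
#' @param codes optional named character vector (substrate -> 10-residue
#'   code) overriding the random draw, e.g. to plant correlated codes for
#'   chemically similar substrates; must be injective.
#' @return list with `pairs` (data.frame adomain_id, substrate), `sequences`
#'   (named character), `codes` (substrate -> planted 10-residue code),
#'   and the generating `spec`.
#' @export
make_adomain_dataset <- function(spec = planted_spec(),
                                 ref = default_reference(), codes = NULL) {
  subs <- spec$substrates
  if (is.null(subs)) {
    mono <- default_monomers()
    subs <- mono$name[mono$class == "amino"][seq_len(spec$n_substrates)]
  }
  if (length(subs) != spec$n_substrates || anyNA(subs)) {
    stop("need ", spec$n_substrates, " substrate names")
  }
  scaffold <- strsplit(ref$reference_sequence, "")[[1]]
  sp <- ref$stachelhaus_positions
  if (!is.null(codes)) {
    stopifnot(setequal(names(codes), subs), !anyDuplicated(codes),
              all(nchar(codes) == 10L))
    codes <- codes[subs]
  }
  withr::with_seed(spec$seed, {
    if (is.null(codes)) {
      # injective codes: draw until distinct (10 residues over 20 letters;
      # collisions essentially impossible, but guard anyway)
      repeat {
        codes <- replicate(spec$n_substrates,
                           paste(sample(AA20, 10, replace = TRUE),
                                 collapse = ""))
        if (!anyDuplicated(codes)) break
      }
      names(codes) <- subs
    }
    ids <- character(0); seqs <- character(0)
    pr_id <- character(0); pr_sub <- character(0)
    for (s in subs) {
      for (r in seq_len(spec$seqs_per_substrate)) {
        id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", s), r)
        sq <- scaffold
        mut <- stats::runif(length(sq)) < spec$mutation_rate
        mut[sp] <- FALSE
        sq[mut] <- sample(AA20, sum(mut), replace = TRUE)
        sq[sp] <- strsplit(codes[[s]], "")[[1]]
        ids <- c(ids, id); seqs <- c(seqs, paste(sq, collapse = ""))
        lab <- s
        if (stats::runif(1) < spec$label_noise) lab <- sample(setdiff(subs, s), 1)
        pr_id <- c(pr_id, id); pr_sub <- c(pr_sub, lab)
        if (stats::runif(1) < spec$promiscuity) {
          pr_id <- c(pr_id, id)
          pr_sub <- c(pr_sub, sample(setdiff(subs, lab), 1))
        }
      }
    }
  })
  names(seqs) <- ids
  list(pairs = data.frame(adomain_id = pr_id, substrate = pr_sub,
                          stringsAsFactors = FALSE),
       sequences = seqs, codes = codes, spec = spec)
}

#' Featurize a generated (or user) sequence set
#'
#' Extracts codes once per sequence and returns the feature matrices the
#' model consumes, plus the 34-residue signatures used for Hamming
#' stratification.
#'
#' @param sequences named character vector of A-domain sequences.
#' @param backend `"onehot"` for the 34 x 21 signature encoding, or an
#'   [embedding_backend()] for 10 x D Stachelhaus-residue features.
#' @param ref a `reference_alignment`.
#' @param cache_dir optional directory; per-sequence results are cached
#'   there keyed by the sequence hash and backend id, so repeated
#'   featurization of large sequence sets is cheap.
#' @return list(features = named list of matrices, signatures = named
#'   character vector, stachelhaus = named character vector).
#' @export
featurize_sequences <- function(sequences, backend = "onehot",
                                ref = default_reference(),
                                cache_dir = NULL) {
  backend_id <- if (identical(backend, "onehot")) "onehot" else {
    stopifnot(inherits(backend, "embedding_backend"))
    backend$id
  }
  one <- function(seq) {
    key <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      tf <- tempfile(); writeLines(c(backend_id, seq), tf)
      key <- file.path(cache_dir, paste0(unname(tools::md5sum(tf)), ".rds"))
      unlink(tf)
      if (file.exists(key)) return(readRDS(key))
    }
    cd <- extract_codes(seq, ref = ref)
    feat <- if (identical(backend, "onehot")) featurize_onehot(cd$signature8A)
      else featurize_residues(seq, ref = ref, backend = backend)
    out <- list(feature = feat, signature = cd$signature8A,
                stachelhaus = cd$stachelhaus)
    if (!is.null(key)) saveRDS(out, key)
    out
  }
  res <- lapply(sequences, one)
  list(features = lapply(res, `[[`, "feature"),
       signatures = vapply(res, `[[`, "", "signature"),
       stachelhaus = vapply(res, `[[`, "", "stachelhaus"))
}

#' Write a generated dataset to TSV
#'
#' Columns: adomain_id, substrate, sequence. Byte-identical for equal spec
#' and seed.
#'
#' @param dataset result of [make_adomain_dataset()].
#' @param path output TSV path.
#' @export
write_pairs_tsv <- function(dataset, path) {
  df <- dataset$pairs
  df$sequence <- dataset$sequences[df$adomain_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sequence/substrate pair table
#'
#' Accepts the TSV schema written by [write_pairs_tsv()] (adomain_id,
#' substrate, sequence) or any table with those columns, e.g. one exported
#' from a curated substrate-annotation repository.
#'
#' @param path TSV path.
#' @return list(pairs, sequences) as in [make_adomain_dataset()].
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("adomain_id", "substrate", "sequence") %in% names(df)))
  seqs <- df$sequence[!duplicated(df$adomain_id)]
  names(seqs) <- df$adomain_id[!duplicated(df$adomain_id)]
  list(pairs = df[, c("adomain_id", "substrate")], sequences = seqs)
}
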