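#' Synthetic BGC genomes
#'
#' Builds toy genomes that encode a blueprinted hybrid BGC: each gene is a
#' single ORF concatenating domain consensus sequences (A-domains are the
#' reference scaffold carrying the planted binding-pocket code of their
#' intended monomer; AT-domains carry a planted 24-residue signature), genes
#' are separated by intergenic spacers, and matching profile HMMs are built
#' on the fly with `hmmbuild` from mutated consensus variants. The truth
#' bundle records coordinates, architectures, intended monomers and module
#' contexts, so mining, graph traversal and assembly can be checked end to
#' end without any downloaded database.
#'
#' @name fixtures_genome
NULL

# fixed codon per amino acid (no stops)
CODON_TABLE <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACC", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(protein) {
  ch <- strsplit(toupper(protein), "")[[1]]
  cod <- CODON_TABLE[ch]
  if (anyNA(cod)) stop("cannot reverse-translate residue(s): ",
                       paste(unique(ch[is.na(cod)]), collapse = ""))
  paste(cod, collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# fixed consensus protein per (non-scaffold) domain class
domain_consensus <- function(class, seed = 101L, length = 60L) {
  if (class == "A") return(default_reference()$reference_sequence)
  if (class == "AT") return(default_at_reference()$reference_sequence)
  withr::with_seed(seed + match(class, DOMAIN_CLASSES), random_protein(length))
}

mutate_protein <- function(protein, rate) {
  ch <- strsplit(protein, "")[[1]]
  mut <- stats::runif(length(ch)) < rate
  ch[mut] <- sample(AA20, sum(mut), replace = TRUE)
  paste(ch, collapse = "")
}

#' Build fixture profile HMMs
#'
#' Writes one aligned FASTA of mutated consensus variants per domain class
#' and compiles them with `hmmbuild` into a single multi-profile HMMER3
#' file. Variants are substitution-only, so the "alignment" is trivially the
#' stacked sequences.
#'
#' @param path output .hmm path.
#' @param classes domain classes to include.
#' @param n_variants sequences per profile (default 10).
#' @param mutation_rate per-residue substitution rate in the variants.
#' @param seed integer.
#' @return `path`, invisibly.
#' @export
make_domain_hmms <- function(path, classes = DOMAIN_CLASSES,
                             n_variants = 10L, mutation_rate = 0.1,
                             seed = 101L) {
  if (!nzchar(Sys.which("hmmbuild"))) stop("hmmbuild not found on PATH")
  tmpd <- tempfile("hmms")
  dir.create(tmpd)
  on.exit(unlink(tmpd, recursive = TRUE), add = TRUE)
  parts <- character(0)
  withr::with_seed(seed, {
    for (cl in classes) {
      cons <- domain_consensus(cl, seed = seed)
      afa <- file.path(tmpd, paste0(cl, ".afa"))
      writeLines(unlist(lapply(seq_len(n_variants), function(i) {
        c(sprintf(">%s_%02d", cl, i), mutate_protein(cons, mutation_rate))
      })), afa)
      hmm <- file.path(tmpd, paste0(cl, ".hmm"))
      st <- system2("hmmbuild", c("-n", cl, "--amino", hmm, afa),
                    stdout = FALSE, stderr = FALSE)
      if (st != 0L) stop("hmmbuild failed for class ", cl)
      parts <- c(parts, hmm)
    }
  })
  out <- file(path, "w")
  for (p in parts) writeLines(readLines(p), out)
  close(out)
  invisible(path)
}

#' Blueprint for a toy BGC genome
#'
#' @param genes list of gene blueprints: each a list with `domains`
#'   (character vector of classes in translation order), `strand` ("+" or
#'   "-"), and `monomers` (intended monomer per active domain, in order).
#' @param intergenic spacer length in bp (default 3000, large enough that
#'   gene calling never fuses adjacent genes).
#' @param margin flanking bp on each contig end.
#' @param codes named substrate -> 10-residue Stachelhaus code map for the
#'   A-domains (normally the `codes` of a [make_adomain_dataset()] run, so
#'   the genome is predictable by a model trained on that dataset).
#' @param at_codes named ketide -> 24-residue AT signature map (normally
#'   from [make_at_training()]).
#' @param seed integer.
#' @return object of class `toy_bgc_spec`.
#' @export
toy_bgc_spec <- function(genes = default_toy_genes(), intergenic = 3000L,
                         margin = 1000L, codes = NULL, at_codes = NULL,
                         seed = 1L) {
  n_active <- sum(vapply(genes, function(g)
    sum(g$domains %in% ACTIVE_CLASSES), 0L))
  stopifnot(n_active >= 1L)
  for (g in genes) {
    stopifnot(all(g$domains %in% DOMAIN_CLASSES),
              length(g$monomers) == sum(g$domains %in% ACTIVE_CLASSES))
  }
  structure(list(genes = genes, intergenic = as.integer(intergenic),
                 margin = as.integer(margin), codes = codes,
                 at_codes = at_codes, seed = as.integer(seed)),
            class = "toy_bgc_spec")
}

#' @rdname toy_bgc_spec
#' @export
default_toy_genes <- function() {
  list(
    list(domains = c("C", "A", "PCP", "C", "A", "PCP", "COM_C"),
         strand = "+", monomers = c("glycine", "alanine")),
    list(domains = c("COM_N", "C", "A", "MT", "PCP", "C", "A", "PCP", "COM_C"),
         strand = "+", monomers = c("valine", "proline")),
    list(domains = c("COM_N", "KS", "AT", "KR", "ACP", "KS", "AT", "ACP"),
         strand = "+", monomers = c("malonyl", "methylmalonyl")),
    list(domains = c("C", "A", "PCP", "C", "A", "PCP", "TE"),
         strand = "+", monomers = c("leucine", "phenylalanine")))
}

plant_code <- function(scaffold, positions, code) {
  ch <- strsplit(scaffold, "")[[1]]
  ch[positions] <- strsplit(code, "")[[1]]
  paste(ch, collapse = "")
}

#' Generate a toy genome with truth bundle
#'
#' @param spec a [toy_bgc_spec()].
#' @param dir output directory; `genome.fna` and `domains.hmm` are written
#'   there.
#' @return invisible list: `genome_fasta`, `hmm_db`, and `truth` (per-gene
#'   coordinates/architecture/monomers/contexts, expected region span, the
#'   expected assembly-line monomer sequence and module contexts).
#' @export
make_toy_genome <- function(spec = toy_bgc_spec(), dir = tempfile("toybgc")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- default_reference()
  at_ref <- default_at_reference()
  codes <- spec$codes
  if (is.null(codes)) {
    codes <- make_adomain_dataset(planted_spec(seed = spec$seed))$codes
  }
  at_codes <- spec$at_codes
  if (is.null(at_codes)) at_codes <- make_at_training(seed = spec$seed)$codes
  linker <- strrep("GS", 5L)
  withr::with_seed(spec$seed, {
    dna_parts <- character(0)
    pos <- 0L
    genes_truth <- list()
    spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
    dna_parts <- c(dna_parts, spacer(spec$margin))
    pos <- spec$margin
    for (gi in seq_along(spec$genes)) {
      bp <- spec$genes[[gi]]
      mono_i <- 0L
      prot <- character(0)
      for (d in bp$domains) {
        if (d == "A") {
          mono_i <- mono_i + 1L
          mono <- bp$monomers[mono_i]
          if (is.null(codes[[mono]])) stop("no planted code for ", mono)
          prot <- c(prot, plant_code(ref$reference_sequence,
                                     ref$stachelhaus_positions, codes[[mono]]))
        } else if (d == "AT") {
          mono_i <- mono_i + 1L
          mono <- bp$monomers[mono_i]
          if (is.null(at_codes[[mono]])) stop("no planted AT code for ", mono)
          prot <- c(prot, plant_code(at_ref$reference_sequence,
                                     at_ref$signature_positions,
                                     at_codes[[mono]]))
        } else {
          prot <- c(prot, domain_consensus(d))
        }
      }
      prot <- paste(prot, collapse = linker)
      dna <- reverse_translate(prot)
      if (bp$strand == "-") {
        dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(dna)))
      }
      genes_truth[[gi]] <- list(index = gi, strand = bp$strand,
                                start = pos, end = pos + nchar(dna),
                                domains = bp$domains,
                                monomers = bp$monomers,
                                contexts = blueprint_contexts(bp$domains))
      dna_parts <- c(dna_parts, dna)
      pos <- pos + nchar(dna)
      if (gi < length(spec$genes)) {
        dna_parts <- c(dna_parts, spacer(spec$intergenic))
        pos <- pos + spec$intergenic
      }
    }
    dna_parts <- c(dna_parts, spacer(spec$margin))
  })
  contig <- paste(dna_parts, collapse = "")
  fa <- file.path(dir, "genome.fna")
  writeLines(c(">toy_contig", contig), fa)
  hmm <- file.path(dir, "domains.hmm")
  make_domain_hmms(hmm, classes = unique(c(unlist(lapply(spec$genes,
                                                         `[[`, "domains")))))
  truth <- list(
    contig = "toy_contig", contig_length = nchar(contig),
    genes = genes_truth,
    region = c(start = max(0L, genes_truth[[1]]$start - 10000L),
               end = min(nchar(contig),
                         genes_truth[[length(genes_truth)]]$end + 10000L)),
    monomers = unlist(lapply(spec$genes, `[[`, "monomers")),
    contexts = unlist(lapply(genes_truth, `[[`, "contexts"),
                      recursive = FALSE),
    has_te = any(vapply(spec$genes, function(g)
      any(g$domains %in% RELEASE_CLASSES), TRUE)),
    codes = codes, at_codes = at_codes, spec = spec)
  invisible(list(genome_fasta = fa, hmm_db = hmm, truth = truth))
}

# tailoring context per active domain of a gene: tailoring classes strictly
# between the active domain and the next active domain; a leading F-domain
# joins the first module
blueprint_contexts <- function(domains) {
  act <- which(domains %in% ACTIVE_CLASSES)
  tails <- c("MT", "F", "Cy", "Ox", "Red", "KR", "DH", "ER")
  out <- list()
  for (ai in seq_along(act)) {
    from <- act[ai] + 1L
    to <- if (ai < length(act)) act[ai + 1L] - 1L else length(domains)
    ctx <- if (from <= to) domains[from:to] else character(0)
    ctx <- ctx[ctx %in% tails]
    if (ai == 1L && act[1] > 1L) {
      lead <- domains[seq_len(act[1] - 1L)]
      ctx <- c(lead[lead == "F"], ctx)
    }
    out[[ai]] <- ctx
  }
  out
}

#' Synthetic AT-domain training data
#'
#' Plants a fixed 24-residue signature per ketide monomer and generates
#' noisy copies for random-forest training.
#'
#' @param monomers ketide monomer names.
#' @param n_per signatures per monomer.
#' @param noise per-position substitution rate in the copies.
#' @param seed integer.
#' @return list(signatures, monomers, codes).
#' @export
make_at_training <- function(monomers = c("malonyl", "methylmalonyl"),
                             n_per = 20L, noise = 0.05, seed = 1L) {
  withr::with_seed(as.integer(seed) + 7919L, {
    codes <- vapply(monomers, function(m)
      paste(sample(AA20, 24L, replace = TRUE), collapse = ""), "")
    sig <- character(0); lab <- character(0)
    for (m in monomers) {
      for (i in seq_len(n_per)) {
        sig <- c(sig, mutate_protein(codes[[m]], noise))
        lab <- c(lab, m)
      }
    }
  })
  list(signatures = sig, monomers = lab, codes = as.list(codes))
}
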