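#' A-domain binding-pocket codes and featurization
#'
#' Adenylation-domain substrate specificity is largely determined by a small
#' set of binding-pocket residues: the classic 10-residue Stachelhaus code and
#' its 34-residue extension covering all residues within 8 angstrom of the
#' pocket. Both codes are extracted by aligning a query A-domain to a single
#' reference A-domain with known code positions and reading off the query
#' residues aligned to those positions.
#'
#' @name adomain_features
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_GAP <- c(AA20, "-")

#' Reference alignment specification
#'
#' Bundles a reference A-domain sequence with the indices (1-based, in the
#' reference) of the 10 Stachelhaus positions and the 34 binding-pocket
#' signature positions. The 10 Stachelhaus positions are not required to be a
#' subset of the 34, although in the shipped reference they are.
#'
#' @param reference_sequence amino-acid string.
#' @param stachelhaus_positions strictly increasing integer vector, length 10.
#' @param signature_positions strictly increasing integer vector, length 34.
#' @return an object of class `reference_alignment`.
#' @export
reference_alignment <- function(reference_sequence, stachelhaus_positions,
                                signature_positions) {
  stopifnot(is.character(reference_sequence), length(reference_sequence) == 1L,
            length(stachelhaus_positions) == 10L,
            length(signature_positions) == 34L,
            all(diff(stachelhaus_positions) > 0),
            all(diff(signature_positions) > 0),
            max(stachelhaus_positions, signature_positions) <=
              nchar(reference_sequence))
  structure(list(reference_sequence = reference_sequence,
                 stachelhaus_positions = as.integer(stachelhaus_positions),
                 signature_positions = as.integer(signature_positions)),
            class = "reference_alignment")
}

#' Load the bundled synthetic A-domain reference
#'
#' The package ships a synthetic reference scaffold (a fixed, randomly drawn
#' A-domain-length sequence) whose Stachelhaus positions follow the GrsA
#' numbering convention (235, 236, 239, 278, 299, 301, 322, 330, 331, 517) and
#' whose 34 signature positions contain the 10 Stachelhaus positions. It is a
#' synthetic stand-in, suitable for planted-signal data and for testing; for
#' production use supply a curated reference via [reference_alignment()].
#'
#' @return a `reference_alignment`.
#' @export
default_reference <- function() {
  path <- system.file("extdata", "synthetic_adomain_reference.json",
                      package = "hybridminer", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_alignment(j$reference_sequence, j$stachelhaus_positions,
                      j$signature_positions)
}

# Map reference positions to query residues through a global alignment.
# Returns a character vector over `positions`; '-' where the reference
# position aligns to a gap in the query.
align_to_reference <- function(sequence, ref, min_identity = 0.3) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 100L) {
    stop("unalignable sequence: shorter than 100 residues")
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(sequence),
    subject = Biostrings::AAString(ref$reference_sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::pid(pa, type = "PID1") < 100 * min_identity) {
    stop(sprintf("unalignable sequence: %.1f%% identity to reference is below %.0f%%",
                 Biostrings::pid(pa, type = "PID1"), 100 * min_identity))
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(sa != "-")
  all_pos <- sort(unique(c(ref$stachelhaus_positions, ref$signature_positions)))
  out <- setNames(rep("-", length(all_pos)), all_pos)
  hit <- match(all_pos, ifelse(sa != "-", ref_pos, NA_integer_))
  found <- !is.na(hit)
  out[found] <- qa[hit[found]]
  out
}

#' Extract the Stachelhaus code and the 34-residue signature
#'
#' @param sequence amino-acid string of the query A-domain (>= 100 residues).
#' @param ref a `reference_alignment`; defaults to the bundled synthetic one.
#' @param min_identity alignment acceptance threshold as fractional identity
#'   over the aligned span (default 0.3).
#' @return list with `stachelhaus` (10-residue string) and `signature8A`
#'   (34-residue string); reference positions aligned to a gap yield '-'.
#' @export
extract_codes <- function(sequence, ref = default_reference(),
                          min_identity = 0.3) {
  res <- align_to_reference(sequence, ref, min_identity)
  list(stachelhaus = paste(res[as.character(ref$stachelhaus_positions)],
                           collapse = ""),
       signature8A = paste(res[as.character(ref$signature_positions)],
                           collapse = ""))
}

#' One-hot encode a 34-residue binding-pocket signature
#'
#' @param signature8A a 34-character string over the 20 amino acids and '-'.
#' @return a 34 x 21 binary matrix; column 21 is the gap column.
#' @export
featurize_onehot <- function(signature8A) {
  ch <- strsplit(toupper(signature8A), "")[[1]]
  stopifnot(length(ch) == 34L)
  idx <- match(ch, AA_GAP)
  if (anyNA(idx)) {
    stop(sprintf("encoding error: unknown residue '%s' in signature",
                 ch[which(is.na(idx))[1]]))
  }
  m <- matrix(0, 34L, 21L, dimnames = list(NULL, AA_GAP))
  m[cbind(seq_len(34L), idx)] <- 1
  m
}

#' Per-residue embedding backends
#'
#' A backend is a deterministic function from an amino-acid sequence to an
#' n x D per-residue embedding matrix. The model extracts the 10 rows at the
#' aligned Stachelhaus positions. The protein-language-model checkpoint used
#' at production scale is not bundled; [plm_backend()] documents the expected
#' interface and fails with guidance when called without a user-supplied
#' embedding function.
#'
#' @param id backend identifier string.
#' @param dim embedding width D.
#' @param fn function(sequence) returning an nchar(sequence) x dim matrix.
#' @return an object of class `embedding_backend`.
#' @export
embedding_backend <- function(id, dim, fn) {
  stopifnot(is.character(id), dim >= 1, is.function(fn))
  structure(list(id = id, dim = as.integer(dim), fn = fn),
            class = "embedding_backend")
}

# fixed physicochemical descriptors per residue: Kyte-Doolittle hydropathy,
# residue volume (A^3)/100, net charge at neutral pH, polarity flag,
# aromaticity flag, H-bond donor/acceptor count scaled
AA_PROPS <- local({
  p <- rbind(
    A = c( 1.8, 0.89,  0.0, 0, 0, 0.0), C = c( 2.5, 1.09,  0.0, 0, 0, 0.5),
    D = c(-3.5, 1.11, -1.0, 1, 0, 1.0), E = c(-3.5, 1.38, -1.0, 1, 0, 1.0),
    F = c( 2.8, 1.90,  0.0, 0, 1, 0.0), G = c(-0.4, 0.60,  0.0, 0, 0, 0.0),
    H = c(-3.2, 1.53,  0.1, 1, 1, 1.0), I = c( 4.5, 1.67,  0.0, 0, 0, 0.0),
    K = c(-3.9, 1.69,  1.0, 1, 0, 1.0), L = c( 3.8, 1.67,  0.0, 0, 0, 0.0),
    M = c( 1.9, 1.63,  0.0, 0, 0, 0.0), N = c(-3.5, 1.14,  0.0, 1, 0, 1.0),
    P = c(-1.6, 1.13,  0.0, 0, 0, 0.0), Q = c(-3.5, 1.44,  0.0, 1, 0, 1.0),
    R = c(-4.5, 1.74,  1.0, 1, 0, 1.5), S = c(-0.8, 0.89,  0.0, 1, 0, 0.5),
    T = c(-0.7, 1.16,  0.0, 1, 0, 0.5), V = c( 4.2, 1.40,  0.0, 0, 0, 0.0),
    W = c(-0.9, 2.28,  0.0, 0, 1, 0.5), Y = c(-1.3, 1.93,  0.0, 1, 1, 1.0))
  colnames(p) <- c("hydropathy", "volume", "charge", "polar", "aromatic", "hbond")
  p
})

#' @rdname embedding_backend
#' @export
physchem_backend <- function() {
  embedding_backend("physchem", ncol(AA_PROPS), function(sequence) {
    ch <- strsplit(toupper(sequence), "")[[1]]
    idx <- match(ch, rownames(AA_PROPS))
    m <- matrix(0, length(ch), ncol(AA_PROPS))
    ok <- !is.na(idx)
    m[ok, ] <- AA_PROPS[idx[ok], , drop = FALSE]
    m
  })
}

#' @rdname embedding_backend
#' @export
onehot_residue_backend <- function() {
  embedding_backend("onehot-residue", 21L, function(sequence) {
    ch <- strsplit(toupper(sequence), "")[[1]]
    idx <- match(ch, AA_GAP)
    idx[is.na(idx)] <- 21L
    m <- matrix(0, length(ch), 21L)
    m[cbind(seq_along(ch), idx)] <- 1
    m
  })
}

#' @rdname embedding_backend
#' @param checkpoint identifier of the per-residue language-model checkpoint
#'   (default the 650M-parameter, 1280-dimensional one).
#' @param embed_fn optional function(sequence) -> n x 1280 matrix wrapping a
#'   language-model inference service.
#' @export
plm_backend <- function(checkpoint = "esm2_t33_650M_UR50D", embed_fn = NULL) {
  if (is.null(embed_fn)) {
    stop("protein-language-model backend '", checkpoint, "' is not bundled; ",
         "supply `embed_fn`, or use the one-hot signature featurization ",
         "(backend = \"onehot\").")
  }
  embedding_backend(paste0("plm:", checkpoint), 1280L, embed_fn)
}

#' Featurize the Stachelhaus residues of an A-domain
#'
#' Computes per-residue embeddings for the whole sequence once, then selects
#' the rows at the 10 query positions aligned to the reference Stachelhaus
#' positions, in reference order. Positions aligned to a gap receive a zero
#' row.
#'
#' @param sequence amino-acid string.
#' @param ref a `reference_alignment`.
#' @param backend an `embedding_backend`.
#' @param min_identity alignment acceptance threshold.
#' @return a 10 x D numeric matrix.
#' @export
featurize_residues <- function(sequence, ref = default_reference(),
                               backend = physchem_backend(),
                               min_identity = 0.3) {
  stopifnot(inherits(backend, "embedding_backend"))
  sequence <- toupper(sequence)
  res <- align_to_reference(sequence, ref, min_identity)
  emb <- backend$fn(sequence)
  stopifnot(nrow(emb) == nchar(sequence), ncol(emb) == backend$dim)
  # query positions of the aligned Stachelhaus residues
  qa_pos <- aligned_query_positions(sequence, ref, min_identity)
  out <- matrix(0, 10L, backend$dim)
  for (i in seq_len(10L)) {
    if (!is.na(qa_pos[i])) out[i, ] <- emb[qa_pos[i], ]
  }
  out
}

# query-coordinate positions aligned to the 10 reference Stachelhaus
# positions; NA where the reference position aligns to a query gap
aligned_query_positions <- function(sequence, ref, min_identity = 0.3) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(sequence)),
    subject = Biostrings::AAString(ref$reference_sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- ifelse(sa != "-", cumsum(sa != "-"), NA_integer_)
  q_pos <- ifelse(qa != "-", cumsum(qa != "-"), NA_integer_)
  cols <- match(ref$stachelhaus_positions, ref_pos)
  q_pos[cols]
}

#' Hamming distance between two binding-pocket signatures
#'
#' @param sigA,sigB equal-length signature strings; the gap character counts
#'   as an ordinary symbol.
#' @return integer count of differing positions.
#' @export
hamming <- function(sigA, sigB) {
  a <- strsplit(sigA, "")[[1]]
  b <- strsplit(sigB, "")[[1]]
  if (length(a) != length(b)) stop("signature length mismatch")
  sum(a != b)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
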