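#' Substrate fingerprints and similarity
#'
#' Substrates (amino acids, hydroxy acids, ketide units and any user-supplied
#' small molecule) are represented by a 296-entry substructure fingerprint:
#' 167 MACCS key bits, a 128-bit Morgan (ECFP, radius 2) vector, and the mean
#' Gasteiger partial charge over the heavy atoms. The fingerprint is the
#' regression target of the specificity model and the input of the latent
#' substrate embedding.
#'
#' @name substrate_chem
NULL

FP_MACCS_LEN <- 167L
FP_MORGAN_LEN <- 128L
FP_LEN <- 296L

ob_fingerprint <- function(smiles, name) {
  res <- ChemmineOB::forEachMol("SMI", paste0(smiles, "\n"), function(m) {
    ChemmineOB::fingerprint_OB(list(m), name)
  })
  as.numeric(res[[1]])
}

fold_bits <- function(bits, width) {
  on <- which(bits != 0) - 1L
  out <- numeric(width)
  out[unique(on %% width) + 1L] <- 1
  out
}

#' Compute the 296-entry substrate fingerprint
#'
#' Entries 1-167 are MACCS key bits, entries 168-295 a Morgan fingerprint of
#' radius 2 folded to 128 bits, entry 296 the mean Gasteiger partial charge.
#'
#' @param smiles a single SMILES string.
#' @return numeric vector of length 296.
#' @examples
#' \dontrun{fp <- compute_fingerprint("NCC(=O)O")  # glycine}
#' @export
compute_fingerprint <- function(smiles) {
  assert_valid_smiles(smiles)
  maccs <- ob_fingerprint(smiles, "MACCS")
  maccs <- as.numeric(maccs[seq_len(FP_MACCS_LEN)] != 0)
  morgan <- fold_bits(ob_fingerprint(smiles, "ECFP4"), FP_MORGAN_LEN)
  fp <- c(maccs, morgan, mean_partial_charge(smiles))
  stopifnot(length(fp) == FP_LEN, all(is.finite(fp)))
  fp
}

#' Mean partial charge of a molecule
#'
#' Gasteiger-type iterative partial equalization charges, averaged over the
#' heavy atoms. Hydrogens are made explicit first so that their charge is not
#' folded into the heavy atoms (otherwise the mean of a neutral molecule is
#' identically zero). Computed with OpenBabel; deterministic, no 3D
#' coordinates involved.
#'
#' @param smiles a single SMILES string.
#' @return a finite numeric scalar.
#' @export
mean_partial_charge <- function(smiles) {
  assert_valid_smiles(smiles)
  out <- suppressWarnings(system2(
    "obabel", c(shQuote(paste0("-:", smiles)), "-h", "-omolreport",
                "--partialcharge", "gasteiger"),
    stdout = TRUE, stderr = FALSE))
  at <- grep("^ATOM:", out, value = TRUE)
  at <- at[!grepl("^ATOM:\\s*\\d+\\s+H\\s", at)]
  ch <- regmatches(at, regexpr("CHARGE:\\s*-?[0-9.]+", at))
  vals <- as.numeric(sub("CHARGE:\\s*", "", ch))
  if (!length(vals) || any(!is.finite(vals))) {
    stop(sprintf("partial charges could not be computed for '%s'", smiles))
  }
  mean(vals)
}

#' Tanimoto similarity between two molecules
#'
#' Bit-set Jaccard similarity on 1024-bit radius-3 Morgan (ECFP6)
#' fingerprints, the benchmark similarity used to compare predicted and true
#' product structures.
#'
#' @param molA,molB SMILES strings.
#' @return numeric in [0, 1]; 1 iff the bit sets are identical.
#' @export
tanimoto <- function(molA, molB) {
  assert_valid_smiles(molA); assert_valid_smiles(molB)
  a <- fold_bits(ob_fingerprint(molA, "ECFP6"), 1024L)
  b <- fold_bits(ob_fingerprint(molB, "ECFP6"), 1024L)
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(1)
  inter / uni
}

#' Build a substrate library
#'
#' Validates and canonicalizes a name/SMILES table, merges duplicates under
#' canonicalization (keeping the first-seen name) and precomputes all
#' fingerprints.
#'
#' @param x a data.frame with columns `name` and `smiles`, or the path of a
#'   TSV file with those columns.
#' @return an object of class `substrate_library` with elements `records`
#'   (data.frame: name, smiles, canonical) and `fingerprints` (numeric matrix,
#'   one named row per substrate).
#' @export
substrate_library <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  stopifnot(all(c("name", "smiles") %in% names(x)), nrow(x) >= 1L)
  canon <- vapply(x$smiles, canonical_smiles, "", USE.NAMES = FALSE)
  keep <- !duplicated(canon)
  rec <- data.frame(name = as.character(x$name)[keep],
                    smiles = as.character(x$smiles)[keep],
                    canonical = canon[keep],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(rec$name)) stop("duplicate substrate names in library")
  fps <- t(vapply(rec$canonical, compute_fingerprint, numeric(FP_LEN),
                  USE.NAMES = FALSE))
  rownames(fps) <- rec$name
  structure(list(records = rec, fingerprints = fps),
            class = "substrate_library")
}

#' @export
print.substrate_library <- function(x, ...) {
  cat(sprintf("<substrate_library: %d substrates, %d-entry fingerprints>\n",
              nrow(x$records), ncol(x$fingerprints)))
  invisible(x)
}

#' @rdname substrate_library
#' @param lib a `substrate_library`.
#' @export
fingerprint_matrix <- function(lib) {
  stopifnot(inherits(lib, "substrate_library"))
  lib$fingerprints
}

#' Export library fingerprints as TSV
#'
#' @param lib a `substrate_library`.
#' @param path output file path.
#' @export
write_fingerprints <- function(lib, path) {
  utils::write.table(fingerprint_matrix(lib), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
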