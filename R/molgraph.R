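#' Molecular graphs
#'
#' A minimal heavy-atom molecular graph used by the assembly and tailoring
#' machinery: atoms carry an element label (and optional per-atom provenance,
#' the index of the monomer an atom came from), bonds carry an integer order.
#' Hydrogens are implicit; valence completion is delegated to OpenBabel when a
#' graph is serialized to SMILES.
#'
#' @param atoms data.frame with column `elem` (element symbol) and optionally
#'   `monomer` (integer provenance).
#' @param bonds data.frame with integer columns `from`, `to`, `order`.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms)
  stopifnot("elem" %in% names(atoms))
  if (is.null(atoms$monomer)) atoms$monomer <- NA_integer_
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  bonds <- as.data.frame(bonds)[, c("from", "to", "order")]
  n <- nrow(atoms)
  if (nrow(bonds)) {
    stopifnot(all(bonds$from >= 1), all(bonds$to >= 1),
              all(bonds$from <= n), all(bonds$to <= n),
              all(bonds$from != bonds$to))
    # canonical bond orientation: from < to
    sw <- bonds$from > bonds$to
    tmp <- bonds$from[sw]; bonds$from[sw] <- bonds$to[sw]; bonds$to[sw] <- tmp
  }
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds> %s\n",
              nrow(x$atoms), nrow(x$bonds),
              tryCatch(molgraph_to_smiles(x), error = function(e) "")))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph` of the heavy atoms.
#' @export
smiles_to_molgraph <- function(smiles) {
  assert_valid_smiles(smiles)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  molgraph(data.frame(elem = elem, stringsAsFactors = FALSE), bonds)
}

# V2000 molfile serialization. ChemmineR's writer cannot emit valid
# fixed-width molblocks for programmatically built SDF objects, so the few
# format lines are produced here directly.
molgraph_to_molblock <- function(g) {
  na <- nrow(g$atoms); nb <- nrow(g$bonds)
  header <- c("", "  hybridminer", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, g$atoms$elem)
  bd <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        g$bonds$from, g$bonds$to, g$bonds$order) else character(0)
  paste(c(header, at, bd, "M  END", ""), collapse = "\n")
}

#' Canonical SMILES of a molecular graph
#'
#' Serializes the heavy-atom graph to a molfile and asks OpenBabel for the
#' canonical SMILES, so chemically identical graphs compare equal as strings.
#'
#' @param g a `molgraph`.
#' @return a canonical SMILES string.
#' @export
molgraph_to_smiles <- function(g) {
  if (nrow(g$atoms) == 0L) stop("empty molecular graph")
  out <- ChemmineOB::convertFormat("MOL", "CAN", molgraph_to_molblock(g))
  smi <- strip_smiles(out)
  if (!nzchar(smi)) stop("molecular graph could not be serialized to SMILES")
  smi
}

strip_smiles <- function(x) sub("[ \t\r\n].*$", "", x)

#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the OpenBabel canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  assert_valid_smiles(smiles)
  strip_smiles(ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")))
}

assert_valid_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    error = function(e) "")
  if (!nzchar(strip_smiles(out))) {
    stop(sprintf("invalid molecule: cannot parse SMILES '%s'", smiles))
  }
  invisible(TRUE)
}

#' Subgraph isomorphism matching (Ullmann-style)
#'
#' Finds all embeddings of a pattern molecular graph into a target molecular
#' graph. An embedding is an injective atom assignment preserving element
#' labels and requiring every pattern bond to be present in the target with
#' the same bond order (substructure semantics: extra target bonds among
#' matched atoms are allowed). Embeddings that cover the same set of target
#' atoms are reported once.
#'
#' @param pattern,target `molgraph` objects.
#' @param unique_sites if `TRUE` (default), deduplicate embeddings by matched
#'   target atom set.
#' @return list of integer vectors; element `i` is the target atom matched to
#'   pattern atom `i`.
#' @export
ullman_match <- function(pattern, target, unique_sites = TRUE) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  if (np == 0L || np > nt) return(list())
  # adjacency with bond order; 0 = no bond
  adj <- function(g, n) {
    m <- matrix(0L, n, n)
    if (nrow(g$bonds)) {
      m[cbind(g$bonds$from, g$bonds$to)] <- g$bonds$order
      m[cbind(g$bonds$to, g$bonds$from)] <- g$bonds$order
    }
    m
  }
  ap <- adj(pattern, np); at <- adj(target, nt)
  degp <- rowSums(ap > 0); degt <- rowSums(at > 0)
  # candidate matrix: element match + degree feasibility
  cand <- lapply(seq_len(np), function(i) {
    which(target$atoms$elem == pattern$atoms$elem[i] & degt >= degp[i])
  })
  if (any(lengths(cand) == 0L)) return(list())
  # order pattern atoms: most constrained first, preferring connectivity
  ord <- order(lengths(cand))
  res <- list()
  assign_vec <- integer(np)
  used <- logical(nt)
  recurse <- function(depth) {
    if (depth > np) {
      res[[length(res) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    i <- ord[depth]
    for (t in cand[[i]]) {
      if (used[t]) next
      ok <- TRUE
      for (dprev in seq_len(depth - 1L)) {
        j <- ord[dprev]
        if (ap[i, j] > 0L && at[t, assign_vec[j]] != ap[i, j]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[i] <<- t; used[t] <<- TRUE
      recurse(depth + 1L)
      used[t] <<- FALSE; assign_vec[i] <<- 0L
    }
    invisible(NULL)
  }
  recurse(1L)
  if (unique_sites && length(res) > 1L) {
    keys <- vapply(res, function(m) paste(sort(m), collapse = ","), "")
    res <- res[!duplicated(keys)]
  }
  res
}
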