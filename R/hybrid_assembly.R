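#' Hybrid core assembly and tailoring
#'
#' Turns an assembly line (ordered genes with monomer predictions) into core
#' molecules and mature products. Amino-acid monomers are joined N-to-C
#' through amide bonds, hydroxy acids through ester bonds (the nitrogen
#' replaced by oxygen), and ketide extender units through decarboxylative
#' C-C bonds that leave a beta-keto group; module-level tailoring domains
#' (methylation, formylation, heterocyclization, ketoreduction/dehydration/
#' enoylreduction) edit the unit they act on; post-assembly modifications are
#' matched into the core by subgraph isomorphism and applied combinatorially
#' over non-overlapping sites, gated on the required enzymes being present in
#' the BGC.
#'
#' @name hybrid_assembly
NULL

# ---- monomer chemistry -------------------------------------------------

# locate carboxyl groups: C with a =O neighbour and a single-bonded O of
# degree 1 (the leaving hydroxyl)
find_carboxyls <- function(g) {
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = nrow(g$atoms))
  res <- list()
  for (c_idx in which(g$atoms$elem == "C")) {
    nb <- g$bonds[g$bonds$from == c_idx | g$bonds$to == c_idx, , drop = FALSE]
    other <- ifelse(nb$from == c_idx, nb$to, nb$from)
    o_dbl <- other[g$atoms$elem[other] == "O" & nb$order == 2]
    o_sgl <- other[g$atoms$elem[other] == "O" & nb$order == 1 & deg[other] == 1]
    if (length(o_dbl) == 1L && length(o_sgl) >= 1L) {
      res[[length(res) + 1L]] <- list(c = c_idx, o_double = o_dbl[1],
                                      o_single = o_sgl[1])
    }
  }
  res
}

neighbors_of <- function(g, i) {
  nb <- g$bonds[g$bonds$from == i | g$bonds$to == i, , drop = FALSE]
  data.frame(atom = ifelse(nb$from == i, nb$to, nb$from), order = nb$order)
}

#' Prepare a monomer for assembly
#'
#' Parses the monomer SMILES and detects its attachment atoms: the donor
#' carboxyl group and the acceptor atom (alpha-amino N, alpha-hydroxy O, or
#' the ketide alpha carbon). Ketide units are returned with the distal
#' carboxyl still attached; it is lost as CO2 on incorporation.
#'
#' @param name monomer name present in the monomer table.
#' @param monomers monomer table (default the bundled one).
#' @return list(graph, class, donor = carboxyl triple, acceptor = atom index
#'   or NA, decarboxylate = atoms removed on incorporation).
#' @export
monomer_unit <- function(name, monomers = default_monomers()) {
  row <- monomers[monomers$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("assembly error: unknown monomer '", name, "'")
  g <- smiles_to_molgraph(row$smiles)
  g$atoms$monomer <- NA_integer_
  cls <- row$class
  cbx <- find_carboxyls(g)
  if (!length(cbx)) stop("assembly error: monomer '", name,
                         "' has no carboxyl attachment")
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = nrow(g$atoms))
  if (cls %in% c("amino", "hydroxy")) {
    want <- if (cls == "amino") "N" else "O"
    donor <- NULL; acceptor <- NA_integer_
    for (cb in cbx) {
      alpha <- neighbors_of(g, cb$c)
      alpha <- alpha$atom[g$atoms$elem[alpha$atom] == "C"]
      for (a in alpha) {
        nb <- neighbors_of(g, a)
        cand <- nb$atom[g$atoms$elem[nb$atom] == want & nb$order == 1 &
                          nb$atom != cb$o_single]
        if (cls == "hydroxy") cand <- cand[deg[cand] == 1]
        if (length(cand)) {
          donor <- cb; acceptor <- cand[1]
          break
        }
      }
      if (!is.null(donor)) break
    }
    if (is.null(donor)) stop("assembly error: monomer '", name,
                             "' lacks an alpha-", want, " attachment")
    list(graph = g, class = cls, donor = donor, acceptor = acceptor,
         decarboxylate = integer(0), name = name)
  } else if (cls == "ketide") {
    if (length(cbx) < 2L) stop("assembly error: ketide monomer '", name,
                               "' needs two carboxyls")
    # alpha carbon bonded to both carboxyl carbons
    cc <- vapply(cbx, `[[`, 0L, "c")
    alpha <- NA_integer_
    for (a in which(g$atoms$elem == "C")) {
      nb <- neighbors_of(g, a)$atom
      if (sum(cc %in% nb) >= 2L) { alpha <- a; break }
    }
    if (is.na(alpha)) stop("assembly error: ketide monomer '", name,
                           "' has no alpha carbon between carboxyls")
    keep <- cbx[[1]]; lose <- cbx[[2]]
    o_extra <- {
      nb <- neighbors_of(g, lose$c)
      nb$atom[g$atoms$elem[nb$atom] == "O"]
    }
    list(graph = g, class = cls, donor = keep, acceptor = alpha,
         decarboxylate = c(lose$c, o_extra), name = name)
  } else stop("assembly error: unknown monomer class '", cls, "'")
}

# remove atoms and renumber; returns list(graph, map old->new index (NA if
# removed))
remove_atoms <- function(g, idx) {
  idx <- unique(idx)
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  map <- rep(NA_integer_, nrow(g$atoms))
  map[keep] <- seq_along(keep)
  b <- g$bonds
  b <- b[!(b$from %in% idx) & !(b$to %in% idx), , drop = FALSE]
  b$from <- map[b$from]; b$to <- map[b$to]
  list(graph = molgraph(g$atoms[keep, , drop = FALSE], b), map = map)
}

add_atom <- function(g, elem, bond_to, order = 1L, monomer = NA_integer_) {
  g$atoms <- rbind(g$atoms, data.frame(elem = elem, monomer = monomer))
  new <- nrow(g$atoms)
  g$bonds <- rbind(g$bonds, data.frame(from = bond_to, to = new,
                                       order = as.integer(order)))
  molgraph(g$atoms, g$bonds)
}

set_bond_order <- function(g, i, j, order) {
  sel <- (g$bonds$from == min(i, j)) & (g$bonds$to == max(i, j))
  if (!any(sel)) {
    g$bonds <- rbind(g$bonds, data.frame(from = min(i, j), to = max(i, j),
                                         order = as.integer(order)))
  } else {
    g$bonds$order[sel] <- as.integer(order)
  }
  molgraph(g$atoms, g$bonds)
}

# maximum total heavy-bond order per element; implicit H fills the rest
MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 6, P = 5, F = 1, Cl = 1, Br = 1, I = 1)

valences_ok <- function(g) {
  tot <- numeric(nrow(g$atoms))
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      tot[g$bonds$from[i]] <- tot[g$bonds$from[i]] + g$bonds$order[i]
      tot[g$bonds$to[i]] <- tot[g$bonds$to[i]] + g$bonds$order[i]
    }
  }
  mx <- MAX_VALENCE[g$atoms$elem]
  mx[is.na(mx)] <- 6
  all(tot <= mx)
}

# ---- core assembly -----------------------------------------------------

#' Assemble a core molecule from a monomer sequence
#'
#' @param monomer_names character vector of monomer names, in assembly
#'   order.
#' @param monomers monomer table.
#' @param release "linear", "macrocycle", or "both" (both is only honoured
#'   when the first monomer offers an amino/hydroxy head atom).
#' @return list of `core_molecule` objects: molgraph with per-atom monomer
#'   provenance, `junctions` (per junction: carbonyl_c, carbonyl_o,
#'   acceptor, type), `cyclic` flag and `monomers`.
#' @export
assemble_core <- function(monomer_names, monomers = default_monomers(),
                          release = "linear") {
  stopifnot(length(monomer_names) >= 1L)
  units <- lapply(monomer_names, monomer_unit, monomers = monomers)
  # initialize with monomer 1 (ketide starters are decarboxylated too)
  u <- units[[1]]
  g <- u$graph
  g$atoms$monomer <- 1L
  head_atom <- if (u$class %in% c("amino", "hydroxy")) u$acceptor else NA_integer_
  if (length(u$decarboxylate)) {
    rm1 <- remove_atoms(g, u$decarboxylate)
    g <- rm1$graph
    head_atom <- if (!is.na(head_atom)) rm1$map[head_atom] else NA_integer_
    donor <- lapply(u$donor, function(i) rm1$map[i])
  } else donor <- u$donor
  junctions <- list()
  for (i in seq_along(units)[-1]) {
    u <- units[[i]]
    m <- u$graph
    m$atoms$monomer <- i
    if (length(u$decarboxylate)) {
      rmk <- remove_atoms(m, u$decarboxylate)
      m <- rmk$graph
      acceptor <- rmk$map[u$acceptor]
      mdonor <- lapply(u$donor, function(x) rmk$map[x])
    } else {
      acceptor <- u$acceptor
      mdonor <- u$donor
    }
    # drop the chain-terminal hydroxyl (condensation water / CO2 already
    # handled for ketides)
    rmo <- remove_atoms(g, donor$o_single)
    g <- rmo$graph
    shift_map <- rmo$map
    head_atom <- if (!is.na(head_atom)) shift_map[head_atom] else NA_integer_
    junctions <- lapply(junctions, function(j) {
      j$carbonyl_c <- shift_map[j$carbonyl_c]
      j$carbonyl_o <- shift_map[j$carbonyl_o]
      j$acceptor <- shift_map[j$acceptor]
      j
    })
    off <- nrow(g$atoms)
    g <- molgraph(rbind(g$atoms, m$atoms),
                  rbind(g$bonds, data.frame(from = m$bonds$from + off,
                                            to = m$bonds$to + off,
                                            order = m$bonds$order)))
    cc <- shift_map[donor$c]
    g <- set_bond_order(g, cc, acceptor + off, 1L)
    junctions[[length(junctions) + 1L]] <- list(
      carbonyl_c = cc, carbonyl_o = shift_map[donor$o_double],
      acceptor = acceptor + off,
      type = switch(u$class, amino = "amide", hydroxy = "ester",
                    ketide = "cc"),
      upstream = i - 1L, downstream = i)
    donor <- lapply(mdonor, function(x) x + off)
  }
  core <- structure(list(graph = g, junctions = junctions,
                         terminal = donor, head_atom = head_atom,
                         cyclic = FALSE, monomers = monomer_names),
                    class = "core_molecule")
  out <- list()
  if (release %in% c("linear", "both")) out <- c(out, list(core))
  if (release %in% c("macrocycle", "both") && !is.na(head_atom) &&
      length(monomer_names) >= 2L) {
    gc <- core
    rmo <- remove_atoms(gc$graph, gc$terminal$o_single)
    gg <- rmo$graph
    mp <- rmo$map
    gg <- set_bond_order(gg, mp[gc$terminal$c], mp[gc$head_atom], 1L)
    gc$graph <- gg
    gc$junctions <- lapply(gc$junctions, function(j) {
      j$carbonyl_c <- mp[j$carbonyl_c]; j$carbonyl_o <- mp[j$carbonyl_o]
      j$acceptor <- mp[j$acceptor]; j
    })
    gc$terminal <- lapply(gc$terminal, function(x) mp[x])
    gc$head_atom <- mp[gc$head_atom]
    gc$cyclic <- TRUE
    out <- c(out, list(gc))
  }
  if (!length(out)) stop("no release variant could be generated")
  out
}

#' @export
print.core_molecule <- function(x, ...) {
  cat(sprintf("<core_molecule: %s%s> %s\n",
              paste(x$monomers, collapse = "-"),
              if (x$cyclic) " (macrocycle)" else "",
              tryCatch(molgraph_to_smiles(x$graph), error = function(e) "")))
  invisible(x)
}

#' @rdname assemble_core
#' @param core a `core_molecule`.
#' @export
core_smiles <- function(core) molgraph_to_smiles(core$graph)

# ---- module tailoring --------------------------------------------------

#' Apply module-level tailoring domains to a core
#'
#' `contexts` lists, per module (monomer position), the tailoring domain
#' classes of that module: "MT" (N-methylation on amino modules,
#' C/O-methylation on ketide modules), "F" (N-formylation, first module
#' only), "Cy" (+ optional "Ox"/"Red") for thiazoline/oxazoline formation on
#' cysteine/serine/threonine-type residues, and "KR"/"DH"/"ER" for the
#' successive beta-keto reductions of ketide units. Inapplicable tailorings
#' are skipped with a warning. Methylation on ketide modules can act on
#' carbon or (when a KR-produced hydroxyl exists) on oxygen, so it may
#' return several variants.
#'
#' @param core a `core_molecule` from [assemble_core()].
#' @param contexts list of character vectors, one per monomer.
#' @param monomers monomer table.
#' @return list of `core_molecule` variants (at least the input, edited).
#' @export
apply_module_tailoring <- function(core, contexts,
                                   monomers = default_monomers()) {
  stopifnot(length(contexts) == length(core$monomers))
  variants <- list(core)
  cls <- monomers$class[match(core$monomers, monomers$name)]
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    if (!length(ctx)) next
    variants <- unlist(lapply(variants, function(v) {
      tailor_module(v, i, ctx, cls[i])
    }), recursive = FALSE)
  }
  variants
}

# amide N of monomer i: junction acceptor for i >= 2, head atom for i == 1
module_nitrogen <- function(core, i) {
  if (i == 1L) {
    if (!is.na(core$head_atom) &&
        core$graph$atoms$elem[core$head_atom] == "N") return(core$head_atom)
    return(NA_integer_)
  }
  for (j in core$junctions) {
    if (j$downstream == i && j$type == "amide") return(j$acceptor)
  }
  NA_integer_
}

upstream_junction <- function(core, i) {
  for (j in core$junctions) if (j$downstream == i) return(j)
  NULL
}

tailor_module <- function(core, i, ctx, cls) {
  g <- core$graph
  if (cls == "ketide") {
    j <- upstream_junction(core, i)
    has_kr <- "KR" %in% ctx; has_dh <- "DH" %in% ctx; has_er <- "ER" %in% ctx
    if ((has_kr || has_dh || has_er) && is.null(j)) {
      warning("ketide reduction on starter module ", i, " skipped: no beta-keto")
    } else if (has_kr && !has_dh) {
      g <- set_bond_order(g, j$carbonyl_c, j$carbonyl_o, 1L) # beta-hydroxy
    } else if (has_kr && has_dh && !has_er) {
      rm <- remove_atoms(g, j$carbonyl_o)
      g <- rm$graph
      core <- remap_core(core, rm$map)
      j <- upstream_junction(core, i)
      g <- set_bond_order(g, j$carbonyl_c, j$acceptor, 2L) # alkene
    } else if (has_kr && has_dh && has_er) {
      rm <- remove_atoms(g, j$carbonyl_o)
      g <- rm$graph
      core <- remap_core(core, rm$map) # fully reduced methylene
    } else if (has_dh || has_er) {
      warning("DH/ER without KR in module ", i, " skipped")
    }
    core$graph <- g
    out <- list(core)
    if ("MT" %in% ctx) {
      # C-methylation at the ketide alpha carbon; O-methylation variant when
      # a KR hydroxyl exists
      res <- list()
      for (v in out) {
        jj <- upstream_junction(v, i)
        if (!is.null(jj)) {
          vc <- v; vc$graph <- add_atom(v$graph, "C", jj$acceptor, 1L,
                                        monomer = i)
          res <- c(res, list(vc))
          if (has_kr && !has_dh &&
              !is.na(jj$carbonyl_o) &&
              v$graph$atoms$elem[jj$carbonyl_o] == "O") {
            vo <- v; vo$graph <- add_atom(v$graph, "C", jj$carbonyl_o, 1L,
                                          monomer = i)
            res <- c(res, list(vo))
          }
        } else {
          warning("C-methylation on starter module ", i, " skipped")
          res <- c(res, list(v))
        }
      }
      out <- res
    }
    return(out)
  }
  # amino / hydroxy modules
  if ("Cy" %in% ctx) {
    core <- heterocyclize(core, i, oxidize = "Ox" %in% ctx,
                          reduce = "Red" %in% ctx)
    g <- core$graph
  }
  if ("MT" %in% ctx) {
    n <- module_nitrogen(core, i)
    if (is.na(n)) {
      warning("N-methylation in module ", i, " skipped: no amide nitrogen")
    } else {
      g <- add_atom(g, "C", n, 1L, monomer = i)
    }
  }
  if ("F" %in% ctx) {
    n <- module_nitrogen(core, i)
    if (i != 1L || is.na(n)) {
      warning("formylation skipped: needs the N-terminal module nitrogen")
    } else {
      g <- add_atom(g, "C", n, 1L, monomer = i)
      g <- add_atom(g, "O", nrow(g$atoms), 2L, monomer = i)
    }
  }
  core$graph <- g
  list(core)
}

remap_core <- function(core, map) {
  core$junctions <- lapply(core$junctions, function(j) {
    j$carbonyl_c <- map[j$carbonyl_c]; j$carbonyl_o <- map[j$carbonyl_o]
    j$acceptor <- map[j$acceptor]; j
  })
  core$terminal <- lapply(core$terminal, function(x) map[x])
  if (!is.na(core$head_atom)) core$head_atom <- map[core$head_atom]
  core
}

# thiazoline / oxazoline: the side-chain S/O of residue i attacks the
# upstream amide carbonyl; the carbonyl oxygen leaves and C=N forms
heterocyclize <- function(core, i, oxidize = FALSE, reduce = FALSE) {
  j <- upstream_junction(core, i)
  if (is.null(j) || j$type != "amide") {
    warning("heterocyclization in module ", i, " skipped: no upstream amide")
    return(core)
  }
  g <- core$graph
  n <- j$acceptor
  alpha <- neighbors_of(g, n)
  alpha <- alpha$atom[g$atoms$elem[alpha$atom] == "C" &
                        alpha$atom != j$carbonyl_c &
                        g$atoms$monomer[alpha$atom] == i]
  side <- NA_integer_; beta <- NA_integer_
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = nrow(g$atoms))
  for (a in alpha) {
    nb <- neighbors_of(g, a)
    bc <- nb$atom[g$atoms$elem[nb$atom] == "C" & nb$order == 1]
    for (b in bc) {
      nb2 <- neighbors_of(g, b)
      if (any(g$atoms$elem[nb2$atom] == "O" & nb2$order == 2)) next # carboxyl
      x <- nb2$atom[g$atoms$elem[nb2$atom] %in% c("O", "S") &
                      nb2$order == 1 & deg[nb2$atom] == 1]
      if (length(x)) { side <- x[1]; beta <- b; break }
    }
    if (!is.na(side)) break
  }
  if (is.na(side)) {
    warning("heterocyclization in module ", i,
            " skipped: residue has no beta-OH/SH side chain")
    return(core)
  }
  rm <- remove_atoms(g, j$carbonyl_o) # cyclodehydration
  g <- rm$graph
  core <- remap_core(core, rm$map)
  j <- upstream_junction(core, i)
  side <- rm$map[side]; beta <- rm$map[beta]; n <- rm$map[n]
  alpha_c <- {
    nb <- neighbors_of(g, beta)
    cand <- nb$atom[nb$atom != side & g$atoms$elem[nb$atom] == "C"]
    cand[1]
  }
  g <- set_bond_order(g, j$carbonyl_c, n, 2L) # C=N imine of the azoline
  g <- set_bond_order(g, side, j$carbonyl_c, 1L) # close the 5-ring
  if (oxidize) g <- set_bond_order(g, alpha_c, beta, 2L) # aromatic azole
  if (reduce) g <- set_bond_order(g, j$carbonyl_c, n, 1L) # azolidine
  core$graph <- g
  core
}

# ---- monomer assignment DP --------------------------------------------

#' Top-s monomer assignments
#'
#' Exact beam-merge dynamic programme: per active domain the candidate
#' monomers with scores are combined left to right, keeping the s
#' best-scoring partial assignments at every step (scores are additive, so
#' the final top-s list is exact). Ties break lexicographically on the
#' monomer sequence.
#'
#' @param predictions list, one data.frame(monomer, score) per active
#'   domain.
#' @param s number of assignments to keep (default 1000).
#' @return data.frame with columns score and monomer_1..monomer_n, sorted by
#'   decreasing score.
#' @export
top_assignments <- function(predictions, s = 1000L) {
  stopifnot(s >= 1L, length(predictions) >= 1L)
  for (p in predictions) {
    if (!nrow(p)) stop("domain with zero monomer predictions")
  }
  beam <- data.frame(score = 0, key = "", stringsAsFactors = FALSE)
  paths <- list(character(0))
  for (d in seq_along(predictions)) {
    p <- predictions[[d]]
    cand_score <- as.vector(outer(p$score, beam$score, "+"))
    cand_prev <- rep(seq_len(nrow(beam)), each = nrow(p))
    cand_mono <- rep(p$monomer, times = nrow(beam))
    key <- paste(beam$key[cand_prev], cand_mono, sep = "\r")
    ord <- order(-cand_score, key)
    keep <- ord[seq_len(min(s, length(ord)))]
    paths <- lapply(keep, function(i) c(paths[[cand_prev[i]]], cand_mono[i]))
    beam <- data.frame(score = cand_score[keep], key = key[keep],
                       stringsAsFactors = FALSE)
  }
  out <- as.data.frame(do.call(rbind, paths), stringsAsFactors = FALSE)
  names(out) <- sprintf("monomer_%d", seq_along(predictions))
  cbind(data.frame(score = beam$score), out)
}

# ---- modifications -----------------------------------------------------

#' Post-assembly modification library
#'
#' Reads a TSV with columns name, motif (a SMILES fragment matched as a
#' labelled subgraph), action (semicolon-separated edits: `attach E@i[:o]`,
#' `order i-j=o`, `bridge E@i-j`, `remove @i`, indices referring to motif
#' atoms in SMILES order) and enzymes (comma-separated required domain
#' classes; empty = constitutive).
#'
#' @param path TSV path; default the bundled fixture library.
#' @return list of `modification` objects.
#' @export
read_modifications <- function(path = system.file("extdata",
                                                  "modifications.tsv",
                                                  package = "hybridminer",
                                                  mustWork = TRUE)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  stopifnot(all(c("name", "motif", "action", "enzymes") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    modification(df$name[i], df$motif[i], df$action[i], df$enzymes[i])
  })
}

#' @rdname read_modifications
#' @param name,motif,action,enzymes see [read_modifications()].
#' @export
modification <- function(name, motif, action, enzymes = "") {
  g <- smiles_to_molgraph(motif)
  ops <- parse_actions(action, nrow(g$atoms))
  enz <- if (!nzchar(trimws(enzymes))) character(0) else
    trimws(strsplit(enzymes, ",")[[1]])
  structure(list(name = name, motif = motif, motif_graph = g, ops = ops,
                 enzymes = enz), class = "modification")
}

parse_actions <- function(action, n_motif) {
  parts <- trimws(strsplit(action, ";")[[1]])
  lapply(parts[nzchar(parts)], function(p) {
    if (grepl("^attach ", p)) {
      m <- regmatches(p, regexec("^attach ([A-Za-z]+)@(\\d+)(:(\\d+))?$", p))[[1]]
      stopifnot(length(m) > 1, as.integer(m[3]) <= n_motif)
      list(op = "attach", elem = m[2], at = as.integer(m[3]),
           order = if (nzchar(m[5])) as.integer(m[5]) else 1L)
    } else if (grepl("^order ", p)) {
      m <- regmatches(p, regexec("^order (\\d+)-(\\d+)=(\\d+)$", p))[[1]]
      stopifnot(as.integer(m[2]) <= n_motif, as.integer(m[3]) <= n_motif)
      list(op = "order", i = as.integer(m[2]), j = as.integer(m[3]),
           order = as.integer(m[4]))
    } else if (grepl("^bridge ", p)) {
      m <- regmatches(p, regexec("^bridge ([A-Za-z]+)@(\\d+)-(\\d+)$", p))[[1]]
      stopifnot(as.integer(m[3]) <= n_motif, as.integer(m[4]) <= n_motif)
      list(op = "bridge", elem = m[2], i = as.integer(m[3]),
           j = as.integer(m[4]))
    } else if (grepl("^remove ", p)) {
      m <- regmatches(p, regexec("^remove @(\\d+)$", p))[[1]]
      stopifnot(as.integer(m[2]) <= n_motif)
      list(op = "remove", at = as.integer(m[2]))
    } else stop("unparseable modification action: ", p)
  })
}

#' Match a modification motif into a core
#'
#' @param core a `core_molecule` (or bare `molgraph`).
#' @param mod a `modification`.
#' @return list of integer mappings (motif atom -> core atom), deduplicated
#'   by matched atom set.
#' @export
match_modification <- function(core, mod) {
  g <- if (inherits(core, "core_molecule")) core$graph else core
  ullman_match(mod$motif_graph, g)
}

# apply a set of non-overlapping (mod, mapping) pairs to a graph
apply_mod_set <- function(g, pairs) {
  removals <- integer(0)
  for (pr in pairs) {
    mp <- pr$mapping
    for (op in pr$mod$ops) {
      if (op$op == "attach") {
        g <- add_atom(g, op$elem, mp[op$at], op$order,
                      monomer = g$atoms$monomer[mp[op$at]])
      } else if (op$op == "order") {
        g <- set_bond_order(g, mp[op$i], mp[op$j], op$order)
      } else if (op$op == "bridge") {
        g <- add_atom(g, op$elem, mp[op$i], 1L,
                      monomer = g$atoms$monomer[mp[op$i]])
        g <- set_bond_order(g, nrow(g$atoms), mp[op$j], 1L)
      } else if (op$op == "remove") {
        removals <- c(removals, mp[op$at])
      }
    }
  }
  if (length(removals)) g <- remove_atoms(g, removals)$graph
  if (!valences_ok(g)) stop("modification set produces invalid valences")
  g
}

#' Gate monomers on pre-assembly enzymes
#'
#' Standard monomers (empty enzyme requirement) are always allowed;
#' conditional monomers require every listed enzyme class among the BGC's
#' domain hits.
#'
#' @param bgc_domains character vector of domain classes present in the BGC.
#' @param monomers monomer table.
#' @return character vector of allowed monomer names.
#' @export
gate_preassembly <- function(bgc_domains, monomers = default_monomers()) {
  ok <- vapply(monomers$enzymes, function(e) {
    if (!nzchar(trimws(e))) return(TRUE)
    all(trimws(strsplit(e, ",")[[1]]) %in% bgc_domains)
  }, TRUE)
  monomers$name[ok]
}

#' Write a product table as SDF
#'
#' Each SMILES in the product table becomes one V2000 record; the product's
#' metadata travel as SDF data fields.
#'
#' @param products data.frame with at least a `smiles` column (e.g. from
#'   [run_pipeline()]).
#' @param path output SDF path.
#' @export
write_products_sdf <- function(products, path) {
  con <- file(path, "w")
  on.exit(close(con))
  extra <- setdiff(names(products), "smiles")
  for (i in seq_len(nrow(products))) {
    g <- smiles_to_molgraph(products$smiles[i])
    block <- sub("^\n", sprintf("product_%d\n", i),
                 molgraph_to_molblock(g))
    writeLines(sub("\n$", "", block), con)
    for (col in extra) {
      writeLines(c(sprintf(">  <%s>", col), as.character(products[[col]][i]),
                   ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Combinatorially apply post-assembly modifications
#'
#' Candidate (modification, site) pairs are the subgraph matches of every
#' modification whose required enzymes are all present in the BGC. Every
#' subset of pairwise non-overlapping pairs (overlap = shared core atoms) is
#' applied, including the empty subset (the unmodified core); products with
#' invalid valences are dropped with a warning, and the result is
#' deduplicated by canonical SMILES.
#'
#' @param core a `core_molecule`.
#' @param mods list of `modification` objects.
#' @param bgc_domains character vector of domain classes present in the BGC.
#' @param max_products cap on emitted products (default 10000); attribute
#'   `truncated` reports whether the cap was hit.
#' @return data.frame with columns smiles and modifications (comma-joined
#'   names, "" for the bare core).
#' @export
apply_postassembly <- function(core, mods, bgc_domains = character(0),
                               max_products = 10000L) {
  gated <- Filter(function(m) all(m$enzymes %in% bgc_domains), mods)
  pairs <- list()
  for (m in gated) {
    for (mp in match_modification(core, m)) {
      pairs[[length(pairs) + 1L]] <- list(mod = m, mapping = mp,
                                          atoms = sort(unique(mp)))
    }
  }
  # deterministic order, independent of input modification order
  if (length(pairs)) {
    keys <- vapply(pairs, function(p)
      paste(p$mod$name, paste(p$atoms, collapse = ","), sep = "|"), "")
    pairs <- pairs[order(keys)]
  }
  np <- length(pairs)
  compat <- matrix(TRUE, np, np)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) for (j in seq(i + 1L, np)) {
      ok <- length(intersect(pairs[[i]]$atoms, pairs[[j]]$atoms)) == 0L
      compat[i, j] <- ok; compat[j, i] <- ok
    }
  }
  results <- list()
  truncated <- FALSE
  emit <- function(subset) {
    if (length(results) >= max_products) { truncated <<- TRUE; return(FALSE) }
    g <- tryCatch(apply_mod_set(core$graph, pairs[subset]),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(g)) {
      smi <- tryCatch(molgraph_to_smiles(g), error = function(e) NULL)
      if (!is.null(smi)) {
        results[[length(results) + 1L]] <<- list(
          smiles = smi,
          modifications = paste(vapply(pairs[subset],
                                       function(p) p$mod$name, ""),
                                collapse = ","))
      }
    }
    TRUE
  }
  recurse <- function(start, chosen) {
    if (!emit(chosen)) return(invisible(NULL))
    if (start > np) return(invisible(NULL))
    for (i in seq(start, np)) {
      if (all(vapply(chosen, function(j) compat[i, j], TRUE))) {
        recurse(i + 1L, c(chosen, i))
      }
    }
    invisible(NULL)
  }
  recurse(1L, integer(0))
  df <- data.frame(
    smiles = vapply(results, `[[`, "", "smiles"),
    modifications = vapply(results, `[[`, "", "modifications"),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df$smiles), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "truncated") <- truncated
  df
}
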