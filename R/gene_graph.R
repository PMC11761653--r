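#' Biosynthetic gene graph
#'
#' Nodes are the genes of a BGC region; a directed edge s -> t means gene t
#' can follow gene s in the biosynthetic assembly. Edges arise from five
#' rules: (R1) s ends in a C-terminal communication (COM) domain and t begins
#' with an N-terminal COM domain; (R2) s ends with a C-domain (A-domain) and
#' t starts with an A-domain (PCP-domain); (R3) t is downstream of s on the
#' same strand; (R4) t contains a release (thioesterase/thioreductase)
#' domain, edges from every other gene; (R5) s is a singleton (exactly one
#' active domain), edges from s to every other gene. Trimming then removes
#' all outgoing edges of release-domain genes and COM-mismatched edges unless
#' removal would orphan the target.
#'
#' @name gene_graph
NULL

#' Build the gene graph from an ordered gene list
#'
#' @param genes list of `bgc_gene` objects.
#' @return object of class `gene_graph`: data.frame `edges` (from, to,
#'   rules), `gene_ids`, and the gene list.
#' @export
build_gene_graph <- function(genes) {
  stopifnot(length(genes) >= 1L)
  ids <- vapply(genes, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  n <- length(genes)
  rules <- matrix("", 0, 3)
  edges <- list()
  add <- function(s, t, rule) {
    edges[[length(edges) + 1L]] <<- c(s, t, rule)
  }
  last2 <- function(d, k) if (length(d)) d[length(d)] else ""
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    gs <- genes[[s]]; gt <- genes[[t]]
    ds <- gs$domains; dt <- gt$domains
    ds_end <- if (length(ds)) ds[length(ds)] else ""
    # domain-logic rules ignore terminal COM domains when reading the last
    # biosynthetic domain of s / first of t
    ds_core <- setdiff_keep(ds, c("COM_N", "COM_C"))
    dt_core <- setdiff_keep(dt, c("COM_N", "COM_C"))
    ds_last <- if (length(ds_core)) ds_core[length(ds_core)] else ""
    dt_first <- if (length(dt_core)) dt_core[1] else ""
    if (gene_ends_ccom(gs) && gene_starts_ncom(gt)) add(s, t, "R1")
    if ((ds_last == "C" && dt_first == "A") ||
        (ds_last == "A" && dt_first == "PCP")) add(s, t, "R2")
    if (gs$strand == gt$strand &&
        ((gs$strand == "+" && gt$start >= gs$end) ||
         (gs$strand == "-" && gt$end <= gs$start))) add(s, t, "R3")
    if (any(dt %in% RELEASE_CLASSES)) add(s, t, "R4")
    if (gene_is_singleton(gs)) add(s, t, "R5")
  }
  ed <- if (length(edges)) {
    m <- do.call(rbind, edges)
    df <- data.frame(from = ids[as.integer(m[, 1])],
                     to = ids[as.integer(m[, 2])],
                     rule = m[, 3], stringsAsFactors = FALSE)
    stats::aggregate(rule ~ from + to, df,
                     function(r) paste(sort(unique(r)), collapse = ","))
  } else data.frame(from = character(0), to = character(0),
                    rule = character(0), stringsAsFactors = FALSE)
  names(ed)[3] <- "rules"
  structure(list(edges = ed[order(ed$from, ed$to), , drop = FALSE],
                 gene_ids = ids, genes = genes),
            class = "gene_graph")
}

setdiff_keep <- function(x, drop) x[!x %in% drop]

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph: %d genes, %d edges>\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Trim the gene graph
#'
#' Removes (i) all outgoing edges of genes containing a release domain, and
#' (ii) edges s -> t where t starts with an N-terminal COM domain but s does
#' not end with a C-terminal COM domain — unless removing all such edges
#' would leave t with no incoming edge (candidate removals are identified
#' first, then the orphan-protection exception applied).
#'
#' @param g a `gene_graph`.
#' @return a trimmed `gene_graph`; never has more edges than the input.
#' @export
trim_gene_graph <- function(g) {
  ed <- g$edges
  by_id <- setNames(g$genes, g$gene_ids)
  release <- vapply(g$genes, gene_has_release, TRUE)
  names(release) <- g$gene_ids
  drop <- release[ed$from]
  # COM-mismatch removals, with orphan protection per target
  mismatch <- vapply(seq_len(nrow(ed)), function(i) {
    gene_starts_ncom(by_id[[ed$to[i]]]) && !gene_ends_ccom(by_id[[ed$from[i]]])
  }, TRUE)
  for (t in unique(ed$to[mismatch])) {
    incoming <- which(ed$to == t & !drop)
    cand <- incoming[mismatch[incoming]]
    if (length(cand) < length(incoming)) {
      drop[cand] <- TRUE
    }
    # else: all surviving incoming edges are mismatched; keep them
  }
  g$edges <- ed[!drop, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Enumerate assembly lines
#'
#' Identifies the sink (minimal out-degree; ties prefer a release-domain
#' gene, then the lowest genomic coordinate) and reports every simple path
#' terminating at the sink with at least n - k nodes, by exhaustive reverse
#' depth-first search. k defaults to the number of singleton genes in the
#' region.
#'
#' @param g a `gene_graph` (normally trimmed).
#' @param k allowed number of inactive (skipped) genes; default = singleton
#'   count.
#' @param max_lines hard cap on emitted paths (default 10000); the result
#'   carries attribute `truncated`.
#' @return list of character vectors (gene-id paths, in assembly order),
#'   sorted deterministically; attribute `sink` names the sink gene.
#' @export
enumerate_assembly_lines <- function(g, k = NULL, max_lines = 10000L) {
  ids <- g$gene_ids
  n <- length(ids)
  if (is.null(k)) k <- sum(vapply(g$genes, gene_is_singleton, TRUE))
  k <- max(0L, as.integer(k))
  outdeg <- vapply(ids, function(i) sum(g$edges$from == i), 0L)
  release <- vapply(g$genes, gene_has_release, TRUE)
  starts <- vapply(g$genes, `[[`, 0L, "start")
  ord <- order(outdeg, !release, starts)
  sink <- ids[ord[1]]
  min_len <- n - k
  # reverse adjacency: predecessors of each node
  preds <- lapply(ids, function(i) sort(g$edges$from[g$edges$to == i]))
  names(preds) <- ids
  res <- list()
  truncated <- FALSE
  path <- character(n)
  visit <- function(node, depth) {
    if (truncated) return(invisible(NULL))
    path[depth] <<- node
    cur <- path[seq_len(depth)]
    if (depth >= min_len || (depth == n)) {
      if (depth >= min_len) {
        if (length(res) >= max_lines) { truncated <<- TRUE; return(invisible(NULL)) }
        res[[length(res) + 1L]] <<- rev(cur)
      }
    }
    for (p in preds[[node]]) {
      if (!p %in% cur) visit(p, depth + 1L)
    }
    invisible(NULL)
  }
  visit(sink, 1L)
  if (length(res) > 1L) {
    keys <- vapply(res, paste, "", collapse = "\r")
    res <- res[order(lengths(res), keys)]
  }
  if (!length(res)) {
    message("no assembly line of length >= ", min_len, " terminates at sink ",
            sink)
  }
  attr(res, "sink") <- sink
  attr(res, "truncated") <- truncated
  res
}

#' Export a gene graph
#'
#' @param g a `gene_graph`.
#' @param path output path; format inferred from the extension (.json or
#'   .dot/.gv).
#' @export
write_gene_graph <- function(g, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(nodes = g$gene_ids, edges = g$edges), path,
                         dataframe = "rows", pretty = TRUE)
  } else {
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        vertices = g$gene_ids)
    igraph::write_graph(ig, path, format = "dot")
  }
  invisible(path)
}
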