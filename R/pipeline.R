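#' End-to-end genome-to-products pipeline
#'
#' Chains mining, annotation, gene-graph traversal, core assembly and
#' post-assembly modification into a single run: genome in, candidate
#' mature-product database out. All stage boundaries are plain data frames
#' and files; a run is a pure function of its inputs and seed.
#'
#' @name pipeline
NULL

# modules of a gene: one entry per active domain with its tailoring context
gene_modules <- function(gene) {
  ctx <- blueprint_contexts(gene$domains)
  act <- which(gene$domains %in% ACTIVE_CLASSES)
  lapply(seq_along(act), function(i) {
    list(class = gene$domains[act[i]], index = act[i],
         context = ctx[[i]], pseq = gene$pseqs[act[i]])
  })
}

#' Run the full pipeline on a genome
#'
#' @param genome FASTA path or named character vector of contigs.
#' @param hmm_db HMMER3 profile file of biosynthetic domain classes.
#' @param model trained `specificity_model` for A-domain annotation.
#' @param mods list of `modification` objects (default the bundled fixture
#'   library).
#' @param monomers monomer table.
#' @param at_forest random forest for AT specificity, or NULL (every AT
#'   falls back to the malonyl-derived default, flagged).
#' @param outdir optional output directory; when given, `products.tsv`,
#'   `regions.json` and `run.json` are written.
#' @param evalue,flank,max_gap mining thresholds (see [mine_bgcs()]).
#' @param k allowed inactive genes (default: singleton count per region).
#' @param s monomer-assignment beam width (default 1000).
#' @param monomer_top_k candidate substrates per A-domain (default 3).
#' @param max_lines,max_products enumeration caps.
#' @param backend,ref,at_ref featurization settings.
#' @return list with `regions`, `products` (data.frame: region, line,
#'   assignment, score, cyclic, smiles, modifications) and `stamp`.
#' @export
run_pipeline <- function(genome, hmm_db, model,
                         mods = read_modifications(),
                         monomers = default_monomers(),
                         at_forest = NULL, outdir = NULL,
                         evalue = 1e-5, flank = 10000L, max_gap = 2000L,
                         k = NULL, s = 1000L, monomer_top_k = 3L,
                         max_lines = 10000L, max_products = 100000L,
                         backend = "onehot", ref = default_reference(),
                         at_ref = default_at_reference()) {
  if (is.character(genome) && length(genome) == 1L && !file.exists(genome)) {
    stop("input genome not found: ", genome)
  }
  regions <- mine_bgcs(genome, hmm_db, evalue = evalue, flank = flank,
                       max_gap = max_gap)
  message(length(regions), " candidate BGC region(s)")
  products <- list()
  for (ri in seq_along(regions)) {
    region <- regions[[ri]]
    ann <- annotate_adomains(region, model, backend = backend, ref = ref,
                             k = monomer_top_k)
    bgc_domains <- unique(region$hits$domain)
    allowed <- gate_preassembly(bgc_domains, monomers)
    graph <- trim_gene_graph(build_gene_graph(region$genes))
    lines <- enumerate_assembly_lines(graph, k = k, max_lines = max_lines)
    genes_by_id <- setNames(region$genes,
                            vapply(region$genes, `[[`, "", "id"))
    seen <- character(0)
    for (li in seq_along(lines)) {
      line <- lines[[li]]
      preds <- list(); contexts <- list(); ok <- TRUE
      for (gid in line) {
        g <- genes_by_id[[gid]]
        for (m in gene_modules(g)) {
          if (m$class == "A") {
            a <- ann[ann$gene == g$id & ann$domain_index == m$index &
                       !is.na(ann$substrate), , drop = FALSE]
            a <- a[a$substrate %in% allowed, , drop = FALSE]
            if (!nrow(a)) next # unknown domain: no monomer constraint
            preds[[length(preds) + 1L]] <-
              data.frame(monomer = a$substrate, score = a$score,
                         stringsAsFactors = FALSE)
          } else {
            res <- tryCatch({
              sig <- at_signature(m$pseq, at_ref)
              if (is.null(at_forest)) {
                list(monomer = "malonyl", score = 0, fallback = TRUE)
              } else at_specificity(sig, at_forest)
            }, error = function(e) list(monomer = "malonyl", score = 0,
                                        fallback = TRUE))
            if (!res$monomer %in% allowed) next
            preds[[length(preds) + 1L]] <-
              data.frame(monomer = res$monomer,
                         score = ifelse(is.na(res$score), 0, res$score),
                         stringsAsFactors = FALSE)
          }
          contexts[[length(contexts) + 1L]] <- m$context
        }
      }
      if (!length(preds)) next
      te_terminal <- gene_has_release(genes_by_id[[line[length(line)]]])
      asg <- top_assignments(preds, s = s)
      for (ai in seq_len(nrow(asg))) {
        mono_seq <- as.character(asg[ai, -1])
        cores <- tryCatch(
          assemble_core(mono_seq, monomers,
                        release = if (te_terminal) "both" else "linear"),
          error = function(e) {
            warning(conditionMessage(e), call. = FALSE)
            NULL
          })
        if (is.null(cores)) next
        for (core in cores) {
          variants <- suppressWarnings(
            apply_module_tailoring(core, contexts, monomers))
          for (v in variants) {
            pp <- suppressWarnings(
              apply_postassembly(v, mods, bgc_domains = bgc_domains,
                                 max_products = max_products))
            if (!nrow(pp)) next
            new <- !pp$smiles %in% seen
            if (!any(new)) next
            seen <- c(seen, pp$smiles[new])
            products[[length(products) + 1L]] <- data.frame(
              region = ri, line = paste(line, collapse = ">"),
              assignment = ai, score = asg$score[ai],
              cyclic = v$cyclic, smiles = pp$smiles[new],
              modifications = pp$modifications[new],
              stringsAsFactors = FALSE)
            if (length(seen) >= max_products) break
          }
          if (length(seen) >= max_products) break
        }
        if (length(seen) >= max_products) break
      }
      if (length(seen) >= max_products) break
    }
  }
  products <- if (length(products)) do.call(rbind, products) else
    data.frame(region = integer(0), line = character(0),
               assignment = integer(0), score = numeric(0),
               cyclic = logical(0), smiles = character(0),
               modifications = character(0), stringsAsFactors = FALSE)
  rownames(products) <- NULL
  stamp <- version_stamp(list(evalue = evalue, flank = flank,
                              max_gap = max_gap, s = s,
                              monomer_top_k = monomer_top_k),
                         libraries = if (is.character(genome) &&
                                         file.exists(hmm_db)) hmm_db else NULL)
  message(nrow(products), " candidate product(s)")
  res <- list(regions = regions, products = products, stamp = stamp)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$products, file.path(outdir, "products.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  regions <- lapply(res$regions, function(r) {
    list(contig = r$contig, start = r$start, end = r$end,
         genes = lapply(r$genes, function(g) {
           list(id = g$id, strand = g$strand, start = g$start, end = g$end,
                domains = g$domains)
         }))
  })
  jsonlite::write_json(regions, file.path(outdir, "regions.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(res$stamp, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Provenance stamp for a run
#'
#' Tool version plus content hashes of the configuration and any library
#' files, so identical inputs yield identical stamps.
#'
#' @param config named list of run parameters.
#' @param libraries character vector of library file paths (or NULL).
#' @return named list (parses to valid JSON via jsonlite).
#' @export
version_stamp <- function(config = list(), libraries = NULL) {
  cfg_file <- tempfile()
  if (length(config)) config <- config[order(names(config))]
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  on.exit(unlink(cfg_file))
  lib_hash <- if (!is.null(libraries)) {
    unname(tools::md5sum(libraries))
  } else character(0)
  list(tool = "hybridminer",
       version = as.character(utils::packageVersion("hybridminer")),
       config = config,
       config_hash = unname(tools::md5sum(cfg_file)),
       library_hashes = lib_hash)
}
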