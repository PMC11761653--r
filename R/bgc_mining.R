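#' Hybrid BGC detection
#'
#' Candidate nonribosomal-peptide / polyketide biosynthetic gene clusters are
#' located by searching profile HMMs of the canonical biosynthetic domains
#' (adenylation A, condensation C, carrier PCP/ACP, acyltransferase AT,
#' ketosynthase KS, release TE/TR, communication COM, and tailoring classes)
#' against the six-frame translation of each contig. Hits are inflated by a
#' flank (10 kb by default) and overlapping segments merged into BGC regions.
#' Genomic coordinates are 0-based half-open throughout.
#'
#' @name bgc_mining
NULL

DOMAIN_CLASSES <- c("A", "C", "PCP", "AT", "KS", "ACP", "TE", "TR",
                    "COM_N", "COM_C", "MT", "F", "Cy", "Ox", "Red",
                    "KR", "DH", "ER")
ACTIVE_CLASSES <- c("A", "AT")
RELEASE_CLASSES <- c("TE", "TR")

#' Six-frame translation with coordinate maps
#'
#' @param contig a DNA string over ACGTN.
#' @return data.frame with columns frame (+1..+3, -1..-3 as integers 1,2,3,
#'   -1,-2,-3), strand, offset and protein; use [frame_to_genomic()] to map a
#'   protein interval back to genomic coordinates.
#' @export
six_frame_translate <- function(contig) {
  if (is.character(contig)) contig <- Biostrings::DNAString(contig)
  L <- length(contig)
  if (L == 0L) stop("empty contig")
  rc <- Biostrings::reverseComplement(contig)
  tr1 <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n <= 0L) return("")
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(s, off + 1L, off + n), if.fuzzy.codon = "solve")))
  }
  out <- data.frame(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    strand = rep(c("+", "-"), each = 3L),
    offset = rep(0:2, 2),
    stringsAsFactors = FALSE)
  out$protein <- c(vapply(0:2, function(o) tr1(contig, o), ""),
                   vapply(0:2, function(o) tr1(rc, o), ""))
  attr(out, "contig_length") <- L
  out
}

#' Map a protein-coordinate interval to genomic coordinates
#'
#' @param frame signed frame (1, 2, 3, -1, -2, -3).
#' @param pstart,pend 1-based inclusive protein positions.
#' @param contig_length length of the contig in nucleotides.
#' @return integer c(start, end), 0-based half-open on the forward strand.
#' @export
frame_to_genomic <- function(frame, pstart, pend, contig_length) {
  off <- abs(frame) - 1L
  s <- off + 3L * (pstart - 1L)
  e <- off + 3L * pend
  if (frame > 0) c(s, e) else c(contig_length - e, contig_length - s)
}

#' @rdname frame_to_genomic
#' @param gstart,gend genomic interval, 0-based half-open.
#' @return integer c(pstart, pend), 1-based inclusive.
#' @export
genomic_to_frame <- function(frame, gstart, gend, contig_length) {
  off <- abs(frame) - 1L
  if (frame < 0) {
    tmp <- gstart
    gstart <- contig_length - gend
    gend <- contig_length - tmp
  }
  c((gstart - off) / 3L + 1L, (gend - off) / 3L)
}

#' Search biosynthetic domains in a genome
#'
#' Delegates the profile search to HMMER's `hmmsearch` over six-frame
#' translations and maps envelope coordinates back to genomic space.
#'
#' @param contigs named character vector / DNAStringSet of contigs, or a
#'   FASTA path.
#' @param hmm_db path to a HMMER3 profile file (one or more profiles; the
#'   profile name is taken as the domain class).
#' @param evalue independent-domain e-value threshold (default 1e-5).
#' @param resolve_overlaps keep only the best-scoring hit among
#'   protein-coordinate-overlapping hits on the same frame (default TRUE).
#' @return data.frame of domain hits: contig, frame, strand, pstart, pend,
#'   gstart, gend, domain, score, evalue, pseq (envelope protein sequence).
#' @export
find_domains <- function(contigs, hmm_db, evalue = 1e-5,
                         resolve_overlaps = TRUE) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  }
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), sub("\\s.*$", "", names(contigs)))
  }
  if (!file.exists(hmm_db)) stop("HMM file not found: ", hmm_db)
  if (!any(grepl("^HMMER3", readLines(hmm_db, n = 1L)))) {
    stop("malformed HMM file (no HMMER3 header): ", hmm_db)
  }
  frames <- lapply(contigs, six_frame_translate)
  # write all frames as one proteome
  fa <- tempfile(fileext = ".faa")
  on.exit(unlink(fa), add = TRUE)
  con <- file(fa, "w")
  for (cn in names(frames)) {
    fr <- frames[[cn]]
    for (i in seq_len(nrow(fr))) {
      if (nchar(fr$protein[i]) == 0L) next
      # stops become X for the search engine; coordinates are unaffected
      writeLines(c(sprintf(">%s|%+d", cn, fr$frame[i]),
                   gsub("*", "X", fr$protein[i], fixed = TRUE)), con)
    }
  }
  close(con)
  empty <- data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), pstart = integer(0),
                      pend = integer(0), gstart = integer(0), gend = integer(0),
                      domain = character(0), score = numeric(0),
                      evalue = numeric(0), pseq = character(0),
                      stringsAsFactors = FALSE)
  if (evalue <= 0) return(empty)
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(tbl), add = TRUE)
  status <- system2("hmmsearch",
                    c("--domtblout", tbl, "--domE", format(evalue),
                      "-E", format(evalue), "--cpu", "1", hmm_db, fa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch failed with status ", status)
  ln <- readLines(tbl)
  ln <- ln[!grepl("^#", ln)]
  if (!length(ln)) return(empty)
  f <- strsplit(trimws(ln), "\\s+")
  hits <- data.frame(
    target = vapply(f, `[`, "", 1L),
    domain = vapply(f, `[`, "", 4L),
    evalue = as.numeric(vapply(f, `[`, "", 13L)),
    score = as.numeric(vapply(f, `[`, "", 14L)),
    pstart = as.integer(vapply(f, `[`, "", 20L)),
    pend = as.integer(vapply(f, `[`, "", 21L)),
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalue, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  sp <- strsplit(hits$target, "|", fixed = TRUE)
  hits$contig <- vapply(sp, `[`, "", 1L)
  hits$frame <- as.integer(vapply(sp, `[`, "", 2L))
  hits$strand <- ifelse(hits$frame > 0, "+", "-")
  gl <- t(mapply(function(ct, fr, ps, pe) {
    frame_to_genomic(fr, ps, pe, nchar(contigs[[ct]]))
  }, hits$contig, hits$frame, hits$pstart, hits$pend))
  hits$gstart <- as.integer(gl[, 1]); hits$gend <- as.integer(gl[, 2])
  hits$pseq <- vapply(seq_len(nrow(hits)), function(i) {
    fr <- frames[[hits$contig[i]]]
    substr(fr$protein[fr$frame == hits$frame[i]], hits$pstart[i], hits$pend[i])
  }, "")
  hits$target <- NULL
  if (resolve_overlaps && nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    for (key in unique(paste(hits$contig, hits$frame))) {
      idx <- which(paste(hits$contig, hits$frame) == key)
      idx <- idx[order(-hits$score[idx])]
      taken <- IRanges::IRanges()
      for (i in idx) {
        r <- IRanges::IRanges(hits$pstart[i], hits$pend[i])
        if (!length(IRanges::findOverlaps(r, taken))) {
          keep[i] <- TRUE
          taken <- c(taken, r)
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$contig, hits$gstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge domain hits into BGC regions
#'
#' Each hit is extended by `flank` on both sides, clipped to the contig, and
#' overlapping or touching segments are merged; regions without any active
#' (A or AT) domain are dropped.
#'
#' @param hits data.frame from [find_domains()].
#' @param contig_lengths named integer vector.
#' @param flank basepairs (default 10000).
#' @return data.frame: contig, start, end (0-based half-open).
#' @export
merge_regions <- function(hits, contig_lengths, flank = 10000L) {
  stopifnot(flank >= 0)
  out <- list()
  for (ct in unique(hits$contig)) {
    h <- hits[hits$contig == ct, , drop = FALSE]
    L <- contig_lengths[[ct]]
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0L, h$gstart - flank) + 1L,
      end = pmin(L, h$gend + flank)))
    for (i in seq_along(ir)) {
      s <- IRanges::start(ir)[i] - 1L; e <- IRanges::end(ir)[i]
      inside <- h$gstart >= s & h$gend <= e
      if (!any(h$domain[inside] %in% ACTIVE_CLASSES)) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Approximate gene calls from domain hits
#'
#' Genes are approximated as maximal runs of same-frame, same-strand domain
#' hits separated by less than `max_gap` basepairs; the domain architecture
#' follows translation order (descending genomic coordinate on the minus
#' strand). Supply annotated CDS boundaries instead when they are available.
#'
#' @param hits data.frame from [find_domains()].
#' @param max_gap maximum intra-gene gap in bp (default 2000).
#' @return list of `bgc_gene` objects.
#' @export
call_genes <- function(hits, max_gap = 2000L) {
  genes <- list()
  for (key in unique(paste(hits$contig, hits$frame))) {
    h <- hits[paste(hits$contig, hits$frame) == key, , drop = FALSE]
    h <- h[order(h$gstart), , drop = FALSE]
    # split runs where the gap to the previous hit is >= max_gap
    gap_break <- c(FALSE, utils::tail(h$gstart, -1) -
                     utils::head(h$gend, -1) >= max_gap)
    run <- cumsum(gap_break)
    for (r in unique(run)) {
      hh <- h[run == r, , drop = FALSE]
      if (hh$strand[1] == "-") hh <- hh[order(-hh$gstart), , drop = FALSE]
      genes[[length(genes) + 1L]] <- bgc_gene(
        id = sprintf("%s_f%+d_%d", hh$contig[1], hh$frame[1],
                     min(hh$gstart)),
        contig = hh$contig[1], strand = hh$strand[1],
        start = min(hh$gstart), end = max(hh$gend),
        domains = hh$domain, pseqs = hh$pseq)
    }
  }
  # deterministic order: by contig then coordinate
  ord <- order(vapply(genes, `[[`, "", "contig"),
               vapply(genes, `[[`, 0L, "start"))
  genes[ord]
}

#' A biosynthetic gene
#'
#' @param id,contig,strand,start,end identity and coordinates (0-based
#'   half-open).
#' @param domains character vector of domain classes in translation order.
#' @param pseqs protein sequences of the domain hits, parallel to `domains`.
#' @return object of class `bgc_gene`.
#' @export
bgc_gene <- function(id, contig = "c", strand = "+", start = 0L, end = 0L,
                     domains = character(0), pseqs = rep("", length(domains))) {
  stopifnot(all(domains %in% DOMAIN_CLASSES))
  structure(list(id = id, contig = contig, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 domains = domains, pseqs = pseqs), class = "bgc_gene")
}

#' @export
print.bgc_gene <- function(x, ...) {
  cat(sprintf("<gene %s [%s%s:%d-%d] %s>\n", x$id, x$contig, x$strand,
              x$start, x$end, paste(x$domains, collapse = "-")))
  invisible(x)
}

gene_n_active <- function(g) sum(g$domains %in% ACTIVE_CLASSES)
gene_is_singleton <- function(g) gene_n_active(g) == 1L
gene_has_release <- function(g) any(g$domains %in% RELEASE_CLASSES)
gene_starts_ncom <- function(g) length(g$domains) > 0 && g$domains[1] == "COM_N"
gene_ends_ccom <- function(g) length(g$domains) > 0 &&
  g$domains[length(g$domains)] == "COM_C"

#' Mine BGC regions from a genome
#'
#' Runs [find_domains()], [merge_regions()] and [call_genes()] and returns
#' one region object per merged segment.
#'
#' @inheritParams find_domains
#' @inheritParams merge_regions
#' @inheritParams call_genes
#' @return list of `bgc_region` objects (contig, start, end, genes, hits).
#' @export
mine_bgcs <- function(contigs, hmm_db, evalue = 1e-5, flank = 10000L,
                      max_gap = 2000L) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  }
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), sub("\\s.*$", "", names(contigs)))
  }
  hits <- find_domains(contigs, hmm_db, evalue = evalue)
  if (!nrow(hits)) return(list())
  lens <- setNames(nchar(contigs), names(contigs))
  regions <- merge_regions(hits, lens, flank = flank)
  lapply(seq_len(nrow(regions)), function(i) {
    sel <- hits$contig == regions$contig[i] &
      hits$gstart >= regions$start[i] & hits$gend <= regions$end[i]
    structure(list(contig = regions$contig[i], start = regions$start[i],
                   end = regions$end[i],
                   genes = call_genes(hits[sel, , drop = FALSE],
                                      max_gap = max_gap),
                   hits = hits[sel, , drop = FALSE]),
              class = "bgc_region")
  })
}

#' @export
print.bgc_region <- function(x, ...) {
  cat(sprintf("<bgc_region %s:%d-%d, %d genes, %d domain hits>\n",
              x$contig, x$start, x$end, length(x$genes), nrow(x$hits)))
  invisible(x)
}

#' Export BGC regions and their genes as GFF3
#'
#' One `region` feature per BGC and one `gene` feature per called gene
#' (with the domain architecture in the attributes). Coordinates follow
#' GFF3 conventions (1-based inclusive).
#'
#' @param regions list of `bgc_region` objects.
#' @param path output GFF3 path.
#' @export
write_regions_gff3 <- function(regions, path) {
  feats <- list()
  for (ri in seq_along(regions)) {
    r <- regions[[ri]]
    feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
      r$contig, IRanges::IRanges(r$start + 1L, r$end),
      strand = "*", type = "region",
      ID = sprintf("bgc_region_%d", ri))
    for (g in r$genes) {
      feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
        r$contig, IRanges::IRanges(g$start + 1L, g$end),
        strand = g$strand, type = "gene", ID = g$id,
        domains = paste(g$domains, collapse = "-"))
    }
  }
  gr <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Annotate the A-domains of a region with substrate predictions
#'
#' Each A-domain hit is featurized and annotated with its top-k substrates;
#' the score is 1 minus the latent cosine distance. A-domains that cannot be
#' aligned to the reference are annotated as unknown (no predictions) with a
#' warning, and contribute no monomer constraint downstream.
#'
#' @param region a `bgc_region`.
#' @param model a trained `specificity_model`.
#' @param backend featurization backend as in [featurize_sequences()].
#' @param ref a `reference_alignment`.
#' @param k predictions per A-domain (default 3).
#' @return data.frame: gene, domain_index, rank, substrate, score.
#' @export
annotate_adomains <- function(region, model, backend = "onehot",
                              ref = default_reference(), k = 3L) {
  out <- list()
  for (g in region$genes) {
    ai <- which(g$domains == "A")
    for (j in ai) {
      res <- tryCatch({
        ft <- featurize_sequences(setNames(g$pseqs[j], "q"), backend = backend,
                                  ref = ref)
        pk <- predict_topk(ft$features[[1]], model, k = k)
        data.frame(gene = g$id, domain_index = j, rank = pk$rank,
                   substrate = pk$substrate, score = 1 - pk$distance,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("A-domain in gene ", g$id, " unalignable: ",
                conditionMessage(e), call. = FALSE)
        data.frame(gene = g$id, domain_index = j, rank = NA_integer_,
                   substrate = NA_character_, score = NA_real_,
                   stringsAsFactors = FALSE)
      })
      out[[length(out) + 1L]] <- res
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), domain_index = integer(0),
                      rank = integer(0), substrate = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' AT-domain signature extraction and specificity
#'
#' The 24-residue active-site signature of an acyltransferase domain is read
#' off an alignment to a reference AT scaffold, one-hot encoded, and
#' classified with a random forest into a ketide extender unit. Top-1 only.
#'
#' @param sequence AT-domain protein sequence.
#' @param at_ref list with `reference_sequence` and 24 `signature_positions`
#'   (default: the bundled synthetic AT reference).
#' @param min_identity alignment acceptance threshold.
#' @return a 24-residue signature string.
#' @export
at_signature <- function(sequence, at_ref = default_at_reference(),
                         min_identity = 0.3) {
  res <- align_to_reference_positions(sequence, at_ref$reference_sequence,
                                      at_ref$signature_positions, min_identity)
  paste(res, collapse = "")
}

#' @rdname at_signature
#' @export
default_at_reference <- function() {
  j <- jsonlite::read_json(system.file("extdata", "synthetic_at_reference.json",
                                       package = "hybridminer", mustWork = TRUE),
                           simplifyVector = TRUE)
  list(reference_sequence = j$reference_sequence,
       signature_positions = as.integer(j$signature_positions))
}

# generic positional read-off through a global alignment
align_to_reference_positions <- function(sequence, ref_seq, positions,
                                         min_identity = 0.3) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(sequence)),
    subject = Biostrings::AAString(ref_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::pid(pa, type = "PID1") < 100 * min_identity) {
    stop("unalignable sequence for signature extraction")
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(sa != "-")
  out <- rep("-", length(positions))
  hit <- match(positions, ifelse(sa != "-", ref_pos, NA_integer_))
  out[!is.na(hit)] <- qa[hit[!is.na(hit)]]
  out
}

#' @rdname at_signature
#' @param signatures character vector of 24-residue signatures.
#' @param monomers character vector of ketide monomer labels.
#' @param seed forest seed.
#' @export
train_at_forest <- function(signatures, monomers, seed = 1L) {
  X <- t(vapply(signatures, function(s) as.vector(onehot24(s)),
                numeric(24L * 21L)))
  withr::with_seed(as.integer(seed), {
    randomForest::randomForest(x = X, y = factor(monomers))
  })
}

onehot24 <- function(signature) {
  ch <- strsplit(toupper(signature), "")[[1]]
  stopifnot(length(ch) == 24L)
  idx <- match(ch, AA_GAP)
  if (anyNA(idx)) stop("encoding error: unknown residue in AT signature")
  m <- matrix(0, 24L, 21L)
  m[cbind(seq_len(24L), idx)] <- 1
  m
}

#' @rdname at_signature
#' @param signature a 24-residue signature.
#' @param forest a forest from [train_at_forest()].
#' @return list(monomer, score, fallback); unalignable/failed inputs fall
#'   back to the malonyl-derived default with `fallback = TRUE`.
#' @export
at_specificity <- function(signature, forest) {
  res <- tryCatch({
    p <- stats::predict(forest, t(as.vector(onehot24(signature))),
                        type = "prob")[1, ]
    list(monomer = names(p)[which.max(p)], score = max(p), fallback = FALSE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    return(list(monomer = "malonyl", score = NA_real_, fallback = TRUE))
  }
  res
}
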