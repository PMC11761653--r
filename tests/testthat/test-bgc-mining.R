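test_that("six-frame translation produces consistent frames and coordinates", {
  withr::with_seed(11, {
    contig <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
  })
  fr <- six_frame_translate(contig)
  expect_equal(nrow(fr), 6L)
  expect_true(all(nchar(fr$protein[fr$offset == 0]) == 20L))
  # codon table sanity on a constructed start
  expect_equal(substr(six_frame_translate("ATGAAACCC")$protein[1], 1, 2), "MK")
  # reverse frames equal forward translation of the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  fr_rc <- six_frame_translate(rc)
  expect_equal(fr$protein[fr$frame == -1L], fr_rc$protein[fr_rc$frame == 1L])
  expect_error(six_frame_translate(""), "empty")
})

test_that("protein/genomic coordinate maps round-trip in all frames", {
  L <- 100L
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    for (pstart in c(1L, 5L)) {
      pend <- pstart + 6L
      g <- frame_to_genomic(frame, pstart, pend, L)
      expect_equal(g[2] - g[1], 3L * (pend - pstart + 1L))
      expect_true(g[1] >= 0L && g[2] <= L)
      back <- genomic_to_frame(frame, g[1], g[2], L)
      expect_equal(back, c(pstart, pend))
    }
  }
})

test_that("domain search finds the planted domains at their coordinates", {
  toy <- fx_toy_genome()
  hits <- find_domains(toy$genome_fasta, toy$hmm_db)
  expect_gt(nrow(hits), 0L)
  truth <- toy$truth
  planted_A <- sum(vapply(truth$genes, function(g)
    sum(g$domains == "A"), 0L))
  expect_equal(sum(hits$domain == "A"), planted_A)
  # each A hit overlaps a gene that declares an A domain
  for (i in which(hits$domain == "A")) {
    covered <- any(vapply(truth$genes, function(g) {
      hits$gstart[i] >= g$start && hits$gend[i] <= g$end &&
        "A" %in% g$domains
    }, TRUE))
    expect_true(covered)
  }
  # coordinates are 0-based half-open within the contig
  expect_true(all(hits$gstart >= 0 & hits$gend <= truth$contig_length))
  # threshold boundary: e-value 0 admits nothing
  expect_equal(nrow(find_domains(toy$genome_fasta, toy$hmm_db, evalue = 0)),
               0L)
  expect_error(find_domains(toy$genome_fasta, tempfile()), "not found")
  bad <- tempfile(); writeLines("not an hmm", bad)
  expect_error(find_domains(toy$genome_fasta, bad), "malformed")
})

test_that("region merging follows the flank arithmetic and drops inactive regions", {
  mk_hit <- function(gstart, gend, domain) {
    data.frame(contig = "c", frame = 1L, strand = "+", pstart = 1L,
               pend = 10L, gstart = gstart, gend = gend, domain = domain,
               score = 50, evalue = 1e-10, pseq = "X")
  }
  lens <- c(c = 100000L)
  # 15 kb apart, 10 kb flank each side: merged
  h <- rbind(mk_hit(10000L, 10300L, "A"), mk_hit(25300L, 25600L, "C"))
  r <- merge_regions(h, lens, flank = 10000L)
  expect_equal(nrow(r), 1L)
  # 25 kb apart: two regions, but the C-only region is dropped
  h2 <- rbind(mk_hit(10000L, 10300L, "A"), mk_hit(35400L, 35700L, "C"))
  r2 <- merge_regions(h2, lens, flank = 10000L)
  expect_equal(nrow(r2), 1L)
  expect_true(r2$start <= 10000L - 10000L + 1L)
  # both active: two regions
  h3 <- rbind(mk_hit(10000L, 10300L, "A"), mk_hit(35400L, 35700L, "AT"))
  expect_equal(nrow(merge_regions(h3, lens, flank = 10000L)), 2L)
  # clipping at the contig edge
  h4 <- mk_hit(100L, 400L, "A")
  r4 <- merge_regions(h4, lens, flank = 10000L)
  expect_equal(r4$start, 0L)
  # merging is idempotent under a naive-sweep oracle
  withr::with_seed(3, {
    gs <- sort(sample.int(80000L, 12L))
    hr <- do.call(rbind, lapply(gs, function(s) mk_hit(s, s + 500L, "A")))
  })
  rr <- merge_regions(hr, lens, flank = 2000L)
  # oracle: naive sweep over inflated intervals
  iv <- cbind(pmax(0L, hr$gstart - 2000L), pmin(lens, hr$gend + 2000L))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
    } else merged <- c(merged, list(iv[i, ]))
  }
  expect_equal(nrow(rr), length(merged))
  expect_equal(rr$start, vapply(merged, `[`, 0L, 1L))
  expect_equal(rr$end, vapply(merged, `[`, 0L, 2L))
})

test_that("gene calling splits same-frame runs at large gaps", {
  toy <- fx_toy_genome()
  regions <- mine_bgcs(toy$genome_fasta, toy$hmm_db)
  expect_length(regions, 1L)
  genes <- regions[[1]]$genes
  expect_length(genes, length(toy$truth$genes))
  for (i in seq_along(genes)) {
    expect_equal(genes[[i]]$domains, toy$truth$genes[[i]]$domains)
    expect_equal(genes[[i]]$strand, toy$truth$genes[[i]]$strand)
  }
})

test_that("AT signatures are 24 residues and the fixture forest recovers them", {
  att <- make_at_training(seed = 7)
  expect_true(all(nchar(att$signatures) == 24L))
  forest <- train_at_forest(att$signatures, att$monomers, seed = 3)
  # planted-signal recovery on the training signatures
  hits <- vapply(seq_along(att$signatures), function(i) {
    at_specificity(att$signatures[i], forest)$monomer == att$monomers[i]
  }, TRUE)
  expect_true(all(hits))
  # one-hot input geometry
  expect_equal(dim(hybridminer:::onehot24(att$signatures[1])), c(24L, 21L))
  # extraction from the reference scaffold
  at_ref <- default_at_reference()
  sig <- at_signature(at_ref$reference_sequence)
  expect_equal(nchar(sig), 24L)
  chars <- strsplit(at_ref$reference_sequence, "")[[1]]
  expect_equal(sig, paste(chars[at_ref$signature_positions], collapse = ""))
  # unalignable input falls back to the malonyl default, flagged
  res <- at_specificity("XXXX", forest)
  expect_true(res$fallback)
  expect_equal(res$monomer, "malonyl")
})

test_that("A-domain annotation attaches top-3 predictions per domain", {
  toy <- fx_toy_genome()
  regions <- mine_bgcs(toy$genome_fasta, toy$hmm_db)
  m <- fx_model()
  ann <- annotate_adomains(regions[[1]], m, k = 3L)
  n_A <- sum(vapply(toy$truth$genes, function(g) sum(g$domains == "A"), 0L))
  expect_equal(nrow(ann), 3L * n_A)
  expect_true(all(ann$score >= -1 & ann$score <= 1))
  # scores descend within each domain
  for (key in unique(paste(ann$gene, ann$domain_index))) {
    s <- ann$score[paste(ann$gene, ann$domain_index) == key]
    expect_true(all(diff(s) <= 0))
  }
  # top-1 matches the planted monomers
  top1 <- ann[ann$rank == 1L, ]
  expect_equal(sort(unique(top1$substrate)),
               sort(unique(unlist(lapply(toy$truth$genes, function(g)
                 g$monomers[g$domains[g$domains %in% c("A", "AT")] == "A"])))))
})

test_that("regions export to GFF3 with genes and architectures", {
  toy <- fx_toy_genome()
  regions <- mine_bgcs(toy$genome_fasta, toy$hmm_db)
  path <- tempfile(fileext = ".gff3")
  write_regions_gff3(regions, path)
  gr <- rtracklayer::import(path)
  expect_equal(sum(gr$type == "region"), length(regions))
  expect_equal(sum(gr$type == "gene"), length(regions[[1]]$genes))
  expect_true(any(grepl("-A-", gr$domains[gr$type == "gene"])))
})
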