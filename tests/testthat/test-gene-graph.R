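# small helpers to build blueprint-level genes at increasing coordinates
gene_row <- function(id, domains, strand = "+", pos = 0L) {
  make_gene(id, domains, strand = strand, start = pos, end = pos + 100L)
}

edge_set <- function(g) paste(g$edges$from, g$edges$to, sep = ">")
has_edge <- function(g, s, t, rule = NULL) {
  sel <- g$edges$from == s & g$edges$to == t
  if (!any(sel)) return(FALSE)
  if (is.null(rule)) return(TRUE)
  rule %in% strsplit(g$edges$rules[sel], ",")[[1]]
}

test_that("each construction rule fires exactly where documented", {
  # R1: COM handshake, independent of position/strand
  g <- build_gene_graph(list(
    gene_row("s", c("C", "A", "PCP", "C", "A", "PCP", "COM_C"), pos = 1000L),
    gene_row("t", c("COM_N", "C", "A", "PCP", "C", "A", "PCP"), pos = 0L,
             strand = "-")))
  expect_true(has_edge(g, "s", "t", "R1"))
  expect_false(has_edge(g, "t", "s"))
  # R2: s ends C, t starts A (terminal COM domains are skipped when reading
  # the flanking biosynthetic domains)
  g <- build_gene_graph(list(
    gene_row("s", c("A", "PCP", "C"), pos = 1000L, strand = "-"),
    gene_row("t", c("A", "PCP"), pos = 2000L, strand = "+")))
  expect_true(has_edge(g, "s", "t", "R2"))
  # R2 mirror: s ends A, t starts PCP
  g <- build_gene_graph(list(
    gene_row("s", c("C", "A"), pos = 1000L, strand = "-"),
    gene_row("t", c("PCP", "C", "A", "PCP"), pos = 0L, strand = "+")))
  expect_true(has_edge(g, "s", "t", "R2"))
  # R3: downstream on the same strand, both orientations
  g <- build_gene_graph(list(
    gene_row("a", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L),
    gene_row("b", c("C", "A", "PCP", "C", "A", "PCP"), pos = 1000L)))
  expect_true(has_edge(g, "a", "b", "R3"))
  expect_false(has_edge(g, "b", "a"))
  g <- build_gene_graph(list(
    gene_row("a", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L, strand = "-"),
    gene_row("b", c("C", "A", "PCP", "C", "A", "PCP"), pos = 1000L,
             strand = "-")))
  expect_true(has_edge(g, "b", "a", "R3"))
  expect_false(has_edge(g, "a", "b"))
  # R4: everyone points at a release-domain gene
  g <- build_gene_graph(list(
    gene_row("a", c("C", "A", "PCP", "C", "A", "PCP"), pos = 2000L),
    gene_row("b", c("C", "A", "PCP", "C", "A", "PCP"), pos = 1000L),
    gene_row("t", c("C", "A", "PCP", "TE"), pos = 0L, strand = "-")))
  expect_true(has_edge(g, "a", "t", "R4"))
  expect_true(has_edge(g, "b", "t", "R4"))
  # R5: singleton (exactly one active domain) points everywhere
  g <- build_gene_graph(list(
    gene_row("s", c("C", "A", "PCP"), pos = 2000L),
    gene_row("x", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L),
    gene_row("y", c("C", "A", "PCP", "C", "A", "PCP"), pos = 1000L)))
  expect_true(has_edge(g, "s", "x", "R5"))
  expect_true(has_edge(g, "s", "y", "R5"))
  # no rule: opposite strands, t upstream, no features
  g <- build_gene_graph(list(
    gene_row("s", c("C", "A", "PCP", "C", "A", "PCP"), pos = 1000L),
    gene_row("t", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L,
             strand = "-")))
  expect_false(has_edge(g, "s", "t"))
  expect_false(has_edge(g, "t", "s"))
})

test_that("trimming removes release outgoing edges and COM mismatches", {
  genes <- list(
    gene_row("g1", c("COM_N", "C", "A", "PCP", "C", "A", "PCP", "COM_C"),
             pos = 0L),
    gene_row("g2", c("COM_N", "C", "A", "PCP", "C", "A", "PCP"), pos = 1000L),
    gene_row("g3", c("KS", "AT", "ACP", "KS", "AT", "ACP"), pos = 2000L),
    gene_row("g4", c("C", "A", "PCP", "TE"), pos = 3000L),
    gene_row("g5", c("C", "A", "PCP", "C", "A", "PCP"), pos = 4000L))
  g <- build_gene_graph(genes)
  gt <- trim_gene_graph(g)
  # release gene g4 keeps no outgoing edges
  expect_true(has_edge(g, "g4", "g5"))
  expect_false(any(gt$edges$from == "g4"))
  # g5 does not end C-COM, g1 starts N-COM, g1 has a C-COM predecessor
  # elsewhere: the mismatched edge goes away
  expect_false(has_edge(gt, "g5", "g1"))
  # g2 starts N-COM and g1 ends C-COM: that edge survives
  expect_true(has_edge(gt, "g1", "g2"))
  expect_lte(nrow(gt$edges), nrow(g$edges))
})

test_that("COM-mismatch removal spares the last incoming edge", {
  # t starts N-COM; its only predecessor does not end C-COM
  genes <- list(
    gene_row("s", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L),
    gene_row("t", c("COM_N", "C", "A", "PCP", "C", "A", "PCP"), pos = 1000L))
  g <- trim_gene_graph(build_gene_graph(genes))
  expect_true(has_edge(g, "s", "t")) # orphan protection
  # with one C-COM and one non-C-COM predecessor, only the mismatch goes
  genes3 <- list(
    gene_row("a", c("C", "A", "PCP", "C", "A", "PCP", "COM_C"), pos = 0L),
    gene_row("b", c("C", "A", "PCP", "C", "A", "PCP"), pos = 500L),
    gene_row("t", c("COM_N", "C", "A", "PCP", "C", "A", "PCP"), pos = 1000L))
  g3 <- trim_gene_graph(build_gene_graph(genes3))
  expect_true(has_edge(g3, "a", "t"))
  expect_false(has_edge(g3, "b", "t"))
})

test_that("a co-linear chain yields exactly one full-length assembly line", {
  genes <- lapply(1:4, function(i) {
    gene_row(paste0("g", i),
             c("C", "A", "PCP", "C", "A", "PCP",
               if (i == 4L) "TE" else NULL),
             pos = i * 1000L)
  })
  g <- trim_gene_graph(build_gene_graph(genes))
  lines <- enumerate_assembly_lines(g, k = 0L)
  expect_length(lines, 1L)
  expect_equal(lines[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(attr(lines, "sink"), "g4")
})

test_that("enumeration equals the exhaustive simple-path oracle", {
  # chain plus singleton shortcuts: denser graph, k = 1
  genes <- c(lapply(1:4, function(i) {
    gene_row(paste0("g", i),
             c("C", "A", "PCP", "C", "A", "PCP",
               if (i == 4L) "TE" else NULL),
             pos = i * 1000L)
  }), list(gene_row("s", c("C", "A", "PCP"), pos = 5000L)))
  g <- trim_gene_graph(build_gene_graph(genes))
  lines <- enumerate_assembly_lines(g, k = 1L)
  sink <- attr(lines, "sink")
  oracle <- oracle_paths_to_sink(g, sink, min_len = length(g$gene_ids) - 1L)
  expect_equal(lines[], oracle, ignore_attr = TRUE)
  expect_true(all(vapply(lines, function(l) l[length(l)] == sink, TRUE)))
})

test_that("co-linear line counts respect the combinatorial upper bound", {
  # for chain-only graphs the number of lines with <= k skips is bounded by
  # sum_{i=0..k} choose(n, i); checked by brute force for n <= 8
  for (n in c(4L, 6L, 8L)) {
    genes <- lapply(seq_len(n), function(i) {
      gene_row(paste0("g", i),
               c("C", "A", "PCP", "C", "A", "PCP",
                 if (i == n) "TE" else NULL),
               pos = i * 1000L)
    })
    g <- trim_gene_graph(build_gene_graph(genes))
    for (k in 0:2) {
      lines <- enumerate_assembly_lines(g, k = k)
      bound <- sum(choose(n, 0:k))
      expect_lte(length(lines), bound)
    }
  }
})

test_that("enumeration order is stable under gene-list permutation", {
  genes <- lapply(1:4, function(i) {
    gene_row(paste0("g", i),
             c("C", "A", "PCP", "C", "A", "PCP",
               if (i == 4L) "TE" else NULL),
             pos = i * 1000L)
  })
  l1 <- enumerate_assembly_lines(trim_gene_graph(build_gene_graph(genes)),
                                 k = 1L)
  l2 <- enumerate_assembly_lines(
    trim_gene_graph(build_gene_graph(genes[c(3, 1, 4, 2)])), k = 1L)
  expect_equal(l1[], l2[], ignore_attr = TRUE)
})

test_that("graphs export to JSON and DOT", {
  genes <- list(gene_row("a", c("C", "A", "PCP", "C", "A", "PCP"), pos = 0L),
                gene_row("b", c("C", "A", "PCP", "TE"), pos = 1000L))
  g <- build_gene_graph(genes)
  j <- tempfile(fileext = ".json")
  write_gene_graph(g, j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(sort(parsed$nodes), c("a", "b"))
  d <- tempfile(fileext = ".dot")
  write_gene_graph(g, d)
  expect_true(any(grepl("->", readLines(d))))
})
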