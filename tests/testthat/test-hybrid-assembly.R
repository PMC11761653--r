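heavy_atoms <- function(core) nrow(core$graph$atoms)
smiles_heavy <- function(s) nrow(smiles_to_molgraph(s)$atoms)

test_that("amide, ester and ketide junction chemistry is correct", {
  # hand-drawn dipeptide, canonicalized by the reference toolchain
  co <- assemble_core(c("glycine", "alanine"))[[1]]
  expect_equal(core_smiles(co), canonical_smiles("NCC(=O)NC(C)C(=O)O"))
  # hydroxy acid: the nitrogen is replaced by oxygen (ester junction)
  es <- assemble_core(c("alanine", "lactate"))[[1]]
  expect_equal(core_smiles(es), canonical_smiles("CC(N)C(=O)OC(C)C(=O)O"))
  # ketide extension: decarboxylative C-C bond leaves a beta-keto group
  ke <- assemble_core(c("glycine", "malonyl"))[[1]]
  expect_equal(core_smiles(ke), canonical_smiles("NCC(=O)CC(=O)O"))
  # single monomer passes through unchanged
  single <- assemble_core("glycine")[[1]]
  expect_equal(core_smiles(single), canonical_smiles("NCC(=O)O"))
  expect_error(assemble_core("no-such-monomer"), "no-such-monomer")
})

test_that("atom counts are conserved at junctions", {
  gly <- smiles_heavy("NCC(=O)O"); ala <- smiles_heavy("CC(N)C(=O)O")
  mal <- smiles_heavy("OC(=O)CC(=O)O")
  # amide loses one water equivalent: 1 heavy atom (the hydroxyl O)
  expect_equal(heavy_atoms(assemble_core(c("glycine", "alanine"))[[1]]),
               gly + ala - 1L)
  # ketide extension loses OH + CO2: 4 heavy atoms from the malonyl side
  expect_equal(heavy_atoms(assemble_core(c("glycine", "malonyl"))[[1]]),
               gly + mal - 4L)
  # chain of three amides: two junctions, two heavy atoms lost
  expect_equal(heavy_atoms(assemble_core(c("glycine", "alanine",
                                           "glycine"))[[1]]),
               2L * gly + ala - 2L)
})

test_that("per-atom monomer provenance covers every heavy atom", {
  co <- assemble_core(c("glycine", "alanine", "valine"))[[1]]
  expect_false(anyNA(co$graph$atoms$monomer))
  expect_equal(sort(unique(co$graph$atoms$monomer)), 1:3)
})

test_that("a terminal thioesterase releases both linear and macrocyclic forms", {
  both <- assemble_core(c("glycine", "alanine", "valine"), release = "both")
  expect_length(both, 2L)
  expect_false(both[[1]]$cyclic)
  expect_true(both[[2]]$cyclic)
  # the macrocycle loses the terminal hydroxyl
  expect_equal(heavy_atoms(both[[2]]), heavy_atoms(both[[1]]) - 1L)
  # head-to-tail cyclic triglycine for a hand check
  cyc <- assemble_core(c("glycine", "glycine", "glycine"),
                       release = "macrocycle")[[1]]
  expect_equal(core_smiles(cyc), canonical_smiles("O=C1CNC(=O)CNC(=O)CN1"))
})

test_that("module tailoring produces the documented edits", {
  # N-methylation after an A-domain loading glycine gives sarcosine
  v <- apply_module_tailoring(assemble_core(c("alanine", "glycine"))[[1]],
                              list(character(0), "MT"))
  expect_length(v, 1L)
  expect_equal(core_smiles(v[[1]]), canonical_smiles("CC(N)C(=O)N(C)CC(=O)O"))
  # KR alone: beta-hydroxy
  v <- apply_module_tailoring(assemble_core(c("glycine", "malonyl"))[[1]],
                              list(character(0), "KR"))
  expect_equal(core_smiles(v[[1]]), canonical_smiles("NCC(O)CC(=O)O"))
  # KR + DH: alkene; KR + DH + ER: methylene
  v <- apply_module_tailoring(assemble_core(c("glycine", "malonyl"))[[1]],
                              list(character(0), c("KR", "DH")))
  expect_equal(core_smiles(v[[1]]), canonical_smiles("NCC=CC(=O)O"))
  v <- apply_module_tailoring(assemble_core(c("glycine", "malonyl"))[[1]],
                              list(character(0), c("KR", "DH", "ER")))
  expect_equal(core_smiles(v[[1]]), canonical_smiles("NCCCC(=O)O"))
  # heterocyclization on a cysteine-loading module forms a thiazoline
  v <- apply_module_tailoring(assemble_core(c("glycine", "cysteine"))[[1]],
                              list(character(0), "Cy"))
  expect_equal(core_smiles(v[[1]]),
               canonical_smiles("NCC1=NC(CS1)C(=O)O"))
  # serine gives the oxazoline analogue
  v <- apply_module_tailoring(assemble_core(c("glycine", "serine"))[[1]],
                              list(character(0), "Cy"))
  expect_equal(core_smiles(v[[1]]),
               canonical_smiles("NCC1=NC(CO1)C(=O)O"))
  # formylation needs the first module; N-formyl glycine dipeptide
  v <- apply_module_tailoring(assemble_core(c("glycine", "alanine"))[[1]],
                              list("F", character(0)))
  expect_equal(core_smiles(v[[1]]),
               canonical_smiles("O=CNCC(=O)NC(C)C(=O)O"))
  # inapplicable tailoring is skipped with a warning, not an error
  expect_warning(
    apply_module_tailoring(assemble_core(c("glycine", "alanine"))[[1]],
                           list(character(0), "Cy")),
    "skipped")
})

test_that("top-s assignment DP is exact against exhaustive enumeration", {
  p1 <- data.frame(monomer = c("a", "b", "c"), score = c(0.9, 0.5, 0.1))
  p2 <- data.frame(monomer = c("x", "y", "z"), score = c(0.8, 0.7, 0.2))
  p3 <- data.frame(monomer = c("m", "n"), score = c(0.6, 0.3))
  # single domain: all candidates sorted
  one <- top_assignments(list(p1), s = 1000L)
  expect_equal(one$monomer_1, c("a", "b", "c"))
  # exhaustive oracle over three domains
  oracle <- expand.grid(m1 = p1$monomer, m2 = p2$monomer, m3 = p3$monomer,
                        stringsAsFactors = FALSE)
  oracle$score <- p1$score[match(oracle$m1, p1$monomer)] +
    p2$score[match(oracle$m2, p2$monomer)] +
    p3$score[match(oracle$m3, p3$monomer)]
  key <- paste(oracle$m1, oracle$m2, oracle$m3, sep = "\r")
  oracle <- oracle[order(-oracle$score, key), ]
  full <- top_assignments(list(p1, p2, p3), s = 1000L)
  expect_equal(nrow(full), 18L)
  expect_equal(full$score, oracle$score)
  expect_equal(full$monomer_1, oracle$m1)
  expect_equal(full$monomer_3, oracle$m3)
  # s truncates the same sorted list
  top2 <- top_assignments(list(p1, p2, p3), s = 2L)
  expect_equal(top2, full[1:2, ], ignore_attr = TRUE)
  expect_error(top_assignments(list(p1[0, ], p2)), "zero")
})

test_that("modification matching and combinatorial application follow the rules", {
  co <- assemble_core(c("glycine", "alanine"))[[1]]
  mods <- read_modifications()
  # no enzymes in the BGC: only the unmodified core
  bare <- apply_postassembly(co, mods, bgc_domains = character(0))
  expect_equal(bare$smiles, core_smiles(co))
  # two modifications sharing one site: none / A / B
  mA <- modification("A", "C(=O)N", "attach C@3", "")
  mB <- modification("B", "C(=O)N", "attach O@3", "")
  shared <- apply_postassembly(co, list(mA, mB))
  expect_equal(nrow(shared), 3L)
  # enzyme gating is a conjunction over required classes
  gated <- modification("G", "C(=O)N", "attach C@3", "MT,Ox")
  expect_equal(nrow(apply_postassembly(co, list(gated),
                                       bgc_domains = "MT")), 1L)
  expect_equal(nrow(apply_postassembly(co, list(gated),
                                       bgc_domains = c("MT", "Ox"))), 2L)
  # product set ignores the input order of the modification list
  p1 <- apply_postassembly(co, mods, bgc_domains = c("MT", "KR"))
  p2 <- apply_postassembly(co, rev(mods), bgc_domains = c("MT", "KR"))
  expect_equal(sort(p1$smiles), sort(p2$smiles))
})

test_that("every modified product re-derives from its core", {
  co <- assemble_core(c("glycine", "alanine", "serine"))[[1]]
  mods <- read_modifications()
  prods <- apply_postassembly(co, mods, bgc_domains = c("MT", "Ox"))
  by_name <- setNames(mods, vapply(mods, `[[`, "", "name"))
  for (i in seq_len(nrow(prods))) {
    applied <- prods$modifications[i]
    if (!nzchar(applied)) {
      expect_equal(prods$smiles[i], core_smiles(co))
      next
    }
    # replay: applying the named modifications over all compatible site
    # choices must reach the recorded product
    names_i <- strsplit(applied, ",")[[1]]
    replayed <- apply_postassembly(co, unname(by_name[unique(names_i)]),
                                   bgc_domains = c("MT", "Ox"))
    expect_true(prods$smiles[i] %in% replayed$smiles)
  }
})

test_that("pre-assembly gating admits conditional monomers only with their enzymes", {
  mono <- default_monomers()
  base <- gate_preassembly(character(0), mono)
  expect_true(all(mono$name[mono$enzymes == ""] %in% base))
  expect_false("N5-hydroxyornithine" %in% base)
  expect_true("N5-hydroxyornithine" %in% gate_preassembly("Ox", mono))
  expect_false("3-methylglutamate" %in% gate_preassembly("MT", mono))
  expect_true("3-methylglutamate" %in% gate_preassembly(c("MT", "Ox"), mono))
})

test_that("a near-miss monomer beats a random swap in product similarity", {
  # two-module chain where the second monomer is mispredicted as a close
  # chemical neighbour; the resulting product stays closer to the truth
  truth <- core_smiles(assemble_core(c("glycine", "leucine"))[[1]])
  near <- core_smiles(assemble_core(c("glycine", "isoleucine"))[[1]])
  far <- core_smiles(assemble_core(c("glycine", "tryptophan"))[[1]])
  expect_gt(tanimoto(near, truth), tanimoto(far, truth))
})

test_that("product tables export to SDF and re-read to the same structures", {
  co <- assemble_core(c("glycine", "alanine"))[[1]]
  prods <- apply_postassembly(co, read_modifications(), bgc_domains = "MT")
  path <- tempfile(fileext = ".sdf")
  write_products_sdf(prods, path)
  sdf <- ChemmineR::read.SDFset(path)
  expect_equal(length(sdf), nrow(prods))
  back <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
  expect_setequal(unname(vapply(back, canonical_smiles, "")),
                  unname(vapply(prods$smiles, canonical_smiles, "")))
})
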