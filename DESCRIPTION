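Package: hybridminer
Title: Adenylation-Domain Substrate Prediction and Hybrid NRP-PK Genome Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the substrate specificity of nonribosomal peptide
    synthetase adenylation (A-) domains by regressing substructure-based
    molecular fingerprints from binding-pocket residue features and
    classifying through nearest-neighbour search in a learned latent
    substrate space, including zero-shot retrieval of substrates absent
    from training. Couples the predictor to a genome-mining engine that
    detects hybrid nonribosomal-peptide / polyketide biosynthetic gene
    clusters with profile HMM searches over six-frame translations, builds
    and traverses a biosynthetic gene graph to enumerate assembly lines,
    assembles candidate core molecules by monomer-assignment dynamic
    programming and connection chemistry, and derives mature products by
    combinatorial application of enzyme-gated tailoring modifications via
    subgraph isomorphism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ChemmineOB,
    ChemmineR,
    GenomicRanges,
    IRanges,
    igraph,
    rtracklayer,
    jsonlite,
    methods,
    randomForest,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (obabel), HMMER3 (hmmbuild, hmmsearch)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
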