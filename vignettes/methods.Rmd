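---
title: "Substrate specificity prediction and hybrid NRP-PK genome mining: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate specificity prediction and hybrid NRP-PK genome mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nonribosomal peptide synthetases (NRPS) and polyketide synthases (PKS) are
assembly lines: each module selects one monomer and condenses it onto the
growing chain. Which monomer an adenylation (A-) domain selects is largely
determined by a handful of binding-pocket residues — the classical
10-residue Stachelhaus code and its 34-residue extension covering all
residues within 8 Å of the pocket. `hybridminer` implements two connected
components:

1. a **substrate-specificity model** that regresses a substructure-based
   molecular fingerprint of the substrate from features of the ten
   binding-pocket residues and classifies by nearest-neighbour search in a
   learned latent substrate space, including *zero-shot* substrates never
   seen in training; and
2. a **genome-mining engine** that detects hybrid NRP-PK biosynthetic gene
   clusters (BGCs) in microbial contigs, enumerates plausible gene orders
   (*assembly lines*) over a biosynthetic gene graph, assembles candidate
   core molecules from per-domain monomer predictions, and derives mature
   products by combinatorial application of enzyme-gated tailoring
   modifications.

## The specificity model

### Fingerprint target

Every substrate is encoded as a 296-entry vector: 167 MACCS key bits, a
128-bit Morgan (ECFP, radius 2) vector, and one real entry holding the mean
Gasteiger partial charge over the heavy atoms. Fingerprints are computed
with OpenBabel (via ChemmineOB). Two deliberate choices:

* **Partial-charge scheme.** No specific charge model is mandated by the
  method itself; we use Gasteiger-type iterative partial equalization
  because it is deterministic and needs no 3D coordinates. Hydrogens are
  made explicit before charging, otherwise OpenBabel folds the hydrogen
  charges into the heavy atoms and the mean of any neutral molecule is
  identically zero. The charge entry is stored raw (unscaled): the cosine
  training loss is scale-tolerant.
* **Morgan bits are presence bits**, folded from OpenBabel's ECFP4 bit
  space to 128 positions by OR; counts are not retained.

The similarity used to compare *product structures* (not training targets)
is the bit-set Jaccard (Tanimoto) on 1024-bit radius-3 Morgan fingerprints.

Stereochemistry is erased throughout; the fingerprints cannot distinguish
stereoisomers, and neither can anything downstream.

### Binding-pocket featurization

Codes are extracted by global pairwise alignment (BLOSUM62, affine gaps,
`Biostrings::pairwiseAlignment`) of the query A-domain against a single
reference A-domain; the query residues aligned to the configured reference
positions are read off, with `-` for reference positions that align to a
gap. Alignments below 30% identity over the aligned span are rejected — the
method itself states no reject rule, but a concrete one is needed; 30% is
well below the identity of any genuine A-domain pair and well above random.

The package ships a **synthetic reference scaffold**
(`inst/extdata/synthetic_adomain_reference.json`): a fixed, randomly drawn
520-residue sequence whose ten Stachelhaus positions follow the GrsA
numbering convention (235, 236, 239, 278, 299, 301, 322, 330, 331, 517) and
whose 34 signature positions contain the ten. The exact 34 positions used
in the structural literature are not available to copy
from, so the shipped positions are a convention, versioned as data, and
replaceable via `reference_alignment()`. The invariant 10th (lysine)
position is retained. The same pattern is used for a synthetic
acyltransferase reference with 24 active-site positions.

Feature backends are pluggable deterministic functions from a sequence to a
per-residue embedding matrix. Bundled: the one-hot encoding of the
34-residue signature (a 34 × 21 indicator matrix, gap column included —
the standard ablation featurization) and a 6-dimensional physicochemical
per-residue embedding. The 1280-dimensional protein-language-model
featurization used at production scale is interface-only here
(`plm_backend()` accepts a user-supplied embedding function and otherwise
fails with guidance); no language model ships with this package, so all
bundled experiments run on the one-hot path.

### Architecture and training

The fingerprint predictor applies two per-residue affine layers
(D → 480 → 240), flattens the residue channels, and finishes with
2400 → 240 → 240 → 296 affine layers; every non-final layer is followed by
ELU and LayerNorm. For the one-hot signature input the same trunk accepts
34 positions of width 21 (flatten width 34 × 240 = 8160): the trunk is
preserved, only the input geometry changes. Training minimizes the batch
mean of per-sample cosine distance `1 - cos(pred, target)` — "averaged
across the fingerprint" is read as averaged across the batch, since cosine
similarity is already a per-vector scalar. Defaults: 80 epochs, batch 128,
AdamW (decoupled weight decay 0.01) at learning rate 1e-4 with ×0.8 decay
every ten epochs.

The classifier head is a 296 → 296 affine layer initialized to the
identity, a ReLU whose output is the **latent substrate embedding**, and a
296 → L affine layer trained with cross-entropy, where L is the number of
unique substrate labels in the training data (derived at fit time, never a
constant). The head is updated twice per predictor step — once on the
predicted fingerprint (with the gradient stopped at the predictor
boundary) and once on the target fingerprint; the predicted-fingerprint
update runs first (the order is not specified anywhere; it is fixed for
reproducibility). Both updates share one optimizer state.

At prediction time the predictor output is embedded through the head and
compared by cosine distance against a database of latent vectors computed
from the *target* fingerprints of all library substrates — which is what
makes zero-shot retrieval work: any substrate with a SMILES can be added to
the database without retraining. Ties in the ranking break
lexicographically by substrate name. Two ablation modes are supported:
nearest search directly in fingerprint space (head bypassed), and direct
classification (trunk ends in L logits, no head).

The whole network stack (forward, reverse-mode gradients, AdamW) is written
in plain R matrix code; gradient correctness is pinned by finite-difference
tests rather than trusted.

## Evaluation protocols

* **Hamming buckets**: a test record is in bucket Bi+ iff the minimum
  Hamming distance of its 34-residue signature to every training signature
  is at least i (defaults 0, 3, 6, 9, 12). Buckets are nested.
* **Top-k accuracy** with a multi-label hit rule: for promiscuous domains
  any observed substrate counts as a hit.
* **Leave-one-substrate-out**: all pairs of one substrate become the test
  set; the substrate remains in the embedding database as a zero-shot
  target.
* **Promiscuous split**: per promiscuous sequence, one random pair trains
  and the remaining n−1 test; seeded.
* **Repeated random splits** default to 12 seeded 80/20 shuffles of unique
  sequences; no canonical ratio exists, so 80/20 is exposed as a
  parameter rather than buried.
* Grouped splits (train on one metadata group, test on another) cover
  cross-taxon transfer without any taxonomic logic.

## Genome mining

Profile HMMs of the domain classes (A, C, PCP, AT, KS, ACP, TE/TR, COM,
and the tailoring classes) are searched with HMMER's `hmmsearch` over the
six-frame translation of each contig; stops are rendered as `X` for the
search engine, and envelope coordinates are mapped back to 0-based
half-open genomic intervals. The default significance threshold is an
independent-domain e-value of 1e-5 — conventional, configurable, and not
prescribed by the method. Overlapping hits on one frame are resolved
best-score-first. Hits are inflated by a 10 kb flank, merged
(`IRanges::reduce`), and regions without an active (A/AT) domain dropped.

Genes on raw contigs are approximated as maximal runs of same-frame,
same-strand hits separated by less than 2 kb; annotated CDS boundaries
should be preferred when available. The production-scale curated HMM
database is user-supplied input; the package builds small fixture HMMs at
run time (`hmmbuild` on synthetic consensus variants) so that every stage
is testable offline.

AT-domain specificity uses a 24-residue active-site signature read off an
alignment to the AT reference and a random forest over the one-hot
encoding; only the top-1 ketide is used. Unalignable ATs fall back to the
malonyl-derived default, flagged.

### The biosynthetic gene graph

Edges arise from five rules (COM handshake; condensation-domain
complementarity; downstream-same-strand; release-domain attraction;
singleton out-edges), each edge tagged with every rule that fires. When a
rule reads the "last" or "first" biosynthetic domain of a gene, terminal
COM domains are skipped, since they are interaction tags rather than
catalytic domains. A *singleton* is a gene with exactly one active (A or
AT) domain. Trimming removes all outgoing edges of release-domain genes,
then COM-mismatched edges, collecting all candidate removals per target
before applying the orphan-protection exception (a target must keep at
least one incoming edge).

The sink is the node with minimal out-degree; ties prefer a release-domain
gene, then the lowest genomic coordinate (release domains terminate
biosynthesis, so this is the biologically sensible tie-break; tie
behaviour is otherwise undefined.) Assembly lines are all simple paths
ending at the sink with at least n−k nodes, enumerated by exhaustive
reverse depth-first search with a configurable cap (default 10 000, with a
truncation flag); k defaults to the singleton count. The combinatorial
upper-bound formulas for line counts are treated as motivation only and
are verified in tests by brute-force enumeration on graphs with n ≤ 8,
not computed as quantities.

## Hybrid assembly chemistry

Monomer candidates per A-domain are the top-3 model predictions (score =
1 − cosine distance); per AT-domain the top-1 forest call. The top-s
monomer assignments (default s = 1000) are found by an exact beam-merge
dynamic programme over the additive per-domain scores, with lexicographic
tie-breaks. Pre-assembly gating admits conditional monomers only when all
their required enzymes have HMM hits in the BGC.

Cores are assembled left to right on heavy-atom molecular graphs with
per-atom monomer provenance: amide bonds for amino acids (the terminal
carboxyl hydroxyl leaves), ester bonds for α-hydroxy acids (nitrogen
replaced by oxygen), and decarboxylative C–C bonds for ketide units (the
distal carboxyl leaves as CO₂ and the upstream carbonyl becomes the
β-keto group). Ketide starters are decarboxylated like extenders; starter
chemistry is not otherwise specified. When the terminal gene carries a
thioesterase, both the linear chain and the head-to-tail macrocycle are
emitted — most reference products are cyclic but the release rule is never
stated, so both variants are kept. Atom-count conservation (one heavy atom
per amide/ester junction, four per ketide junction counting the leaving
hydroxyl) is asserted in tests on every fixture assembly.

Module-level tailoring edits the unit the domain context belongs to:
N-formylation (F, first module), N-methylation (methylation domain after an
A-domain), C- or O-methylation (after an AT-domain; the O variant only
exists when a ketoreductase-produced hydroxyl is present, so both variants
are emitted then), thiazoline/oxazoline formation (heterocyclization after
an A-domain loading a β-SH/OH residue, with optional ring oxidation or
reduction), and the successive β-keto reductions KR → hydroxyl, KR+DH →
alkene, KR+DH+ER → methylene. Inapplicable tailorings skip with a warning
rather than failing the variant.

Post-assembly modifications are (motif, rewrite, required-enzyme) triples;
motifs are SMILES fragments matched into the core as labelled subgraphs by
an Ullmann-style matcher (element and bond-order labels, substructure
semantics, embeddings deduplicated by matched atom set). A modification is
considered only when all its required enzyme classes hit in the BGC.
Products are all subsets of pairwise non-overlapping (modification, site)
pairs — overlap means shared atoms, the strictest consistent reading of
single-site mutual exclusion — applied to the core, including the empty
subset, deduplicated by canonical SMILES, valence-checked, and capped with
a truncation flag. Module-tailoring variants multiply with post-assembly
subsets (capped); deduplication across
assembly lines is unstated, so the pipeline deduplicates per region.

The shipped modification library (12 entries) and monomer table (27
entries) are deliberately small fixture libraries exercising every rewrite
primitive (`attach`, `order`, `bridge`, `remove`); production use expects
curated user-supplied tables in the same TSV schema.

## What the synthetic data does and does not show

The planted-signal generator writes a distinct random 10-residue code per
substrate into the scaffold's Stachelhaus positions and mutates the rest of
the sequence at 10% per residue; promiscuity adds a second random label to
a sequence, label noise replaces labels. It emulates exactly the structural
assumption of the model — binding-pocket residues determine specificity —
and none of the confounders of real data: no phylogenetic correlation
between sequences, no chemistry-correlated code similarity (except where a
test plants it deliberately), no class imbalance, no alignment ambiguity.
Passing the planted-signal tests therefore demonstrates that the
implementation can recover a clean signal under the default training
procedure; it says nothing about accuracy on natural A-domains, which
depends on the language-model featurization and curated training data that
are out of scope here.

The zero-shot fixture plants the held-out substrate's binding-pocket code
one residue away from a chemical near-twin: phenylalanine is held out with
leucine as the twin, because phenylalanine is leucine's nearest library
fingerprint under the bundled metric. The precondition — the held-out
substrate is the nearest library entry to the mean fingerprint of the
cluster it is planted into — is asserted explicitly before the retrieval
rate is measured, so a passing retrieval rate measures zero-shot behaviour
rather than luck.

The promiscuity ablation maps each sequence to two chemically dissimilar
substrates (glycine/tryptophan, alanine/tyrosine, serine/phenylalanine)
and retrieves against a database larger than the label set, so that
midpoint fingerprint predictions meet distractor substrates in fingerprint
space but not in the label-trained latent space; the latent-vs-fingerprint
comparison is asserted on the mean true-substrate rank averaged over three
fixed seeds, since single runs at this scale are noisy in either
direction.

The toy genome encodes a four-gene hybrid cluster (two NRPS genes, one
two-module PKS gene, one terminal NRPS gene with a thioesterase) as single
ORFs of concatenated domain consensus sequences with planted codes,
3 kb intergenic spacers and fixture HMMs built on the fly. Its truth
bundle (coordinates, architectures, monomers, contexts) lets mining, graph
traversal and assembly be compared against blueprint-level expectations;
the core chemistry itself is pinned against hand-drawn SMILES in separate
unit tests.

## Problem sizes and numerical choices

Bundled experiments use 8 substrates × 40 sequences (the training run),
the same with one substrate held out (zero-shot), 8 × 15 with full
promiscuity (ablation direction checks), and a ~25 kb toy genome. These
sizes are chosen so every documented experiment reruns from scratch in
minutes on a laptop core while still forcing the planted signal through
the full 80-epoch default training schedule.

Numerical details: LayerNorm uses ε = 1e-5; Glorot-uniform initialization
everywhere except the identity-initialized head; all randomness flows from
a single recorded seed per training run (`withr::with_seed`), and two runs
with equal seeds produce identical parameters. Cosine distance on a zero
vector is an error by contract; latent vectors are strictly nonnegative by
construction and nonzero in practice because every fingerprint sets MACCS
bits. Degenerate inputs (empty contigs, empty libraries, domains without
predictions, unalignable sequences) error or warn per the documented
contracts rather than propagating silently.

## Known limitations

* No bundled protein-language-model featurization; the one-hot path is the
  default and the PLM path is an interface.
* Iterative (type II) PKS logic, stereochemistry, thioester-level
  energetics, and mass-spectrometry-based product filtering are out of
  scope.
* Gene calling on raw contigs is a domain-run heuristic; use annotated CDS
  where possible.
* The Ullmann matcher matches element/bond-order labels, not full SMARTS
  semantics (no aromaticity perception beyond the Kekulé structures both
  sides are parsed into, no wildcards); motifs in the modification table
  are written accordingly.
* OpenBabel's MACCS definitions differ in a few patterns from other
  toolkits' MACCS implementations; fingerprints are internally consistent
  but not bit-for-bit comparable across toolkits.
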