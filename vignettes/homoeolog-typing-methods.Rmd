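---
title: "Methods: homoeolog typing and polyploid origin inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog typing and polyploid origin inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeoPhy)
```

# The problem

Polyploid plants carry multiple copies of every nuclear gene. When a
polyploid arose by hybridization between two species followed by genome
doubling (an *allopolyploid*), its gene copies — *homoeologs* — descend
from two different parental lineages; when it arose by doubling within a
single species (an *autopolyploid*), the copies are duplicates of a single
lineage. A low-copy nuclear gene amplified across a set of diploid and
polyploid individuals therefore carries a readable signature of the mode
of polyploid origin: in a gene tree, an autopolyploid's copies should be
each other's closest relatives, whereas an allopolyploid's homoeologs fall
into different major clades, each closer to copies from other species than
to each other.

homoeoPhy implements this inference end-to-end for an amplicon of a
granule-bound starch synthase class gene (*GBSS*I-1 type) spanning the tail
of exon 3 through the head of exon 8, with complete introns 3–7. In the
group this design targets, the gene occurs in structural variants
distinguished purely by intron architecture: the ancestral form (here
called 1a) has a long fourth intron; a derived form (1b) carries a large
deletion in intron 4; a further derived form (1c) has additionally lost
intron 5 entirely. Because allotetraploids combine one 1a-pool copy with
one 1b/1c-pool copy, structural typing and tree placement reinforce each
other.

# Pipeline stages

## Exon/intron annotation by boundary projection

Amplicons are annotated by projecting the exon/intron boundaries of an
annotated reference through a global pairwise alignment
(Needleman–Wunsch, affine gaps; match +2, mismatch −3, gap open 5, gap
extend 2, a gap run of length $L$ costing $\mathrm{open} + \mathrm{extend}
\cdot L$). Each projected intron boundary is then snapped to the nearest
position within ±`snapWindow` (default 6 bp) at which the intron begins
`GT` and ends `AG`, the canonical spliceosomal dinucleotides. Snapping
prefers the smallest displacement, zero first, so an intact boundary is
never moved. When no canonical dinucleotide lies in the window the
boundary is kept at its projected position and flagged non-canonical — a
warning, not an error, since a mutated splice site is itself evidence of
pseudogenization. An intron whose projected span falls below
`minIntronLen` (default 20 bp) is recorded as *lost* with length 0: a
handful of residual bases cannot be a functional intron, and a small
positive floor separates complete intron loss from short alleles.
Queries covering less than 50% of the reference are rejected.

All coordinates are 0-based, half-open. Segment tables always tile the
sequence; validity methods on the S4 classes enforce this.

## Structural-variant typing

The classifier is a pure function of intron lengths:

* intron 4 shorter than `tau4` (default 300 bp) **and** intron 5 at or
  below `intron5LostMax` (default 20 bp) → **V1C**;
* intron 4 short alone → **V1B**;
* otherwise (intron 5 present) → **V1A**;
* the combination never seen in real data — long intron 4 with lost
  intron 5 — → **UNCLASSIFIED**.

The 300 bp threshold sits in the wide gap between the observed long-form
intron-4 lengths (403–484 bp) and short-form lengths (191–249 bp), so the
call is insensitive to tens of base pairs of indel noise. The deficit of
the query's intron 4 against the reference is reported alongside as a
cross-check statistic but is not part of the rule, because an
absolute-length rule reproduces the published classes while a
deficit-only rule is sensitive to reference choice.

## Pseudogene detection

Exonic segments are concatenated and translated in the frame anchored by
the reference annotation (the amplicon is gene-internal, so *any* stop
codon is internal). A sequence is flagged a putative pseudogene when its
exonic length differs from the reference by a non-multiple of 3
(frameshift) or its translation contains a stop. Codons containing IUPAC
ambiguity codes translate to `X` and never count as stops. Exonic regions
shorter than one codon yield an *undetermined* report. Pseudogenes keep
their structural variant label — a decayed copy still records which
lineage donated it — and bypass the amino-acid orthology screen, whose
identity statistic is meaningless on a frameshifted translation.

## Orthology screen

Queries are screened by translating their exons and aligning the protein
globally against the translated reference exons (BLOSUM62, gap open 10,
extend 0.5). The screen passes at ≥ 90% identity over ≥ 100 aligned
residues. An E-value is not computed: it belongs to database-search
engines and adds nothing over identity on a fixed locus. Outgroup
sequences are exempt from screening for the purpose of tree building —
distant outgroups legitimately fail an ortholog-identity criterion yet
are required for rooting.

## Alignment statistics and distances

Gaps (`-`), `?` and all IUPAC ambiguity codes count as missing data
throughout. A column is *variable* when at least two distinct unambiguous
bases occur in it and *parsimony-informative* when at least two bases
each occur in at least two sequences; columns with no unambiguous base
are *all-missing*. Percentages are reported against the aligned length to
two decimals. Uncorrected p-distances are mismatches over comparable
sites, with pairwise deletion by default (complete deletion available);
a pair with zero comparable sites is an error, not a zero.

## Tree building and supports

Trees are built by Saitou–Nei neighbor joining on the p-distance matrix.
Ties in the Q-criterion break toward the lowest index pair, and negative
branch-length estimates are clamped to zero with the deficit transferred
to the sister edge, so the output is deterministic and satisfies the
non-negative length invariant. Bootstrap supports resample alignment
columns with replacement; each internal edge of the full-data tree is
annotated with the percentage of replicate trees containing the same
bipartition (computed by canonicalized bipartition keys; replicates in
which some pair loses all comparable sites are skipped and counted, with
a warning above 5%). Supports are invariant to the input leaf order.
Rooting requires the outgroup to form one side of a bipartition of the
unrooted tree; otherwise a rooting error names the offending set, and the
pipeline falls back to rooting on the first outgroup leaf.

## Origin inference

For each individual with $k$ gene copies in the rooted, support-annotated
tree:

* $k = 1$ → **UNINFORMATIVE** (single copy);
* copies monophyletic (their MRCA subtends exactly them) →
  **AUTOPOLYPLOID_PATTERN**;
* copies non-monophyletic and assigned to two distinct major clades with
  separating support ≥ `supportMin` (default 70) →
  **ALLOPOLYPLOID_PATTERN**;
* anything else → **UNINFORMATIVE**, with the reason recorded.

Major clades are anchored by exemplar sequences; by default the pipeline
derives them from the typing itself — clade I is anchored by every typed
V1A sequence, clade II by every V1B/V1C sequence, excluding outgroups —
because the two major clades of the gene tree comprise all sequences of
the respective variants, from diploids and polyploids alike. A sequence
is assigned to a clade when it descends from the MRCA of that clade's
exemplars and of no other clade's; sequences under neither or both are
unassigned.

The *separating support* of a copy pair is the support of the
best-supported edge whose bipartition places one copy together with its
clade's exemplars on one side and the other copy with its exemplars on
the other. This deliberately differs from "the support of the exemplar
MRCA node": near the base of a dense radiation the exemplar MRCA's own
edge may be an arbitrary, weakly supported local resolution, while the
deep split that actually separates the two gene pools is maximally
supported — and it is that split which carries the evidence for
allopolyploidy. The minimum over copy pairs is recorded in the call.

Two conventions from the source system are kept: a diploid whose two
alleles show the allopolyploid-style placement is reported with the
display label `hybrid-pattern` (interspecific hybridization without
doubling), and when an externally supplied tree carries no supports at
all, gating is disabled and calls are flagged "unsupported-tree mode".
The default support floor of 70 is the conventional bootstrap threshold
for "well supported"; the clades this pipeline relies on are typically
supported at 84–100, so the conclusions are insensitive to the exact
floor.

# The synthetic-data generator

`simulateDataset()` produces datasets with the statistical structure the
analysis assumes, plus complete ground truth (per-sequence variant
lineage and pseudogene status, per-individual origin mode, the generating
tree, and a gap-tracked true alignment), so every stage is testable
without any external data. The generative model:

* A synthetic annotated reference (1291 bp; exon stubs of 7 bp flanking
  complete exons 4–7 and introns 3–7; intron 4 of 440 bp; stop-free
  reading frame) is the root state. It is constructed deterministically
  and is labelled synthetic — it carries no real sequence.
* Two diploid gene pools, A and B, split at the root. `stemDepth`
  (default 0.08 expected substitutions/site) is the **tip-to-root
  depth**, so the expected between-pool path length is $2 \cdot
  \mathrm{stemDepth}$ and the expected between-pool p-distance follows
  the JC69 closed form $\tfrac34\,(1 - e^{-8\,\mathrm{stemDepth}/3})$
  exactly on the sites evolving at the nominal rate.
* Pool B's stem carries the structural deletion of
  `intron4DeletionBp` (default 280 bp) from the centre of intron 4;
  designated B lineages (`intron5LossIn`) additionally lose intron 5
  entirely on their terminal branch, creating the 1c form.
* Within each pool, the sampled diploid lineages follow a random
  bifurcating ultrametric genealogy whose joins fall in the upper 30%
  of the crown (`crownDepth`, default 0.02). This shape gives every
  lineage a long terminal branch and no true polytomies. A plain
  coalescent shape was rejected: its coalescences concentrate near the
  tips, leaving within-pool sequences nearly identical after rescaling.
* Substitutions follow JC69. Exon sites substitute at `exonRateScale`
  (default 0.2) times the intron rate — purifying selection on a
  conserved enzyme — which keeps congeneric amino-acid identity in the
  mid-90s, as a >90% orthology screen presupposes. Splice-site
  dinucleotides are protected from substitution, and exonic
  substitutions that would create an in-frame stop are reverted, so
  functional copies stay functional and pseudogene ground truth is
  exactly the set of dedicated pseudogenization events.
* Intron indels occur at `intronIndelRate` (default 0.3) events per
  intron per branch with geometric lengths (mean `indelLenMean` = 8 bp),
  confined to intron interiors so splice sites and boundary projection
  are never disturbed by the indel process itself.
* Each polyploid's parental gene lineages diverge from *within* the
  sampled radiation: a parent is sister to one sampled diploid lineage,
  splitting from its terminal branch at a height drawn so that copy
  coalescence (`polyploidTipDepth`, default 0.004), parent divergence,
  and the sister's own divergence are three distinct events, each
  leaving an expected handful of substitutions. Allopolyploids draw one
  parent from each pool; autopolyploids draw one parent and duplicate
  it with two independent terminal branches. The exact progenitor
  individual of a polyploid is essentially never among the sampled
  diploids, which this construction reflects.
* Each emitted sequence is pseudogenized with probability
  `pseudogeneRate` (default 0.03) by a 1–2 bp exonic indel — always a
  frameshift, matching the observation that such pseudogenes arise from
  exonic indels.
* Two outgroup taxa forming their own small clade are emitted at
  `outgroupDepth` (default 0.15). Rooting on a two-tip outgroup clade is
  far more stable than on one long branch, and mirrors the practice of
  rooting with two outgroup genera.

Alignment-column bookkeeping: every base carries a numeric column key
inherited from the ancestor; insertions draw fresh keys strictly between
their neighbours. The union of keys across sequences defines the true
multiple alignment, so the alignment-consuming stages (site statistics,
distances, trees) are testable without an external aligner — the package
deliberately consumes alignments rather than producing them. Insertions
on different lineages are mutually non-homologous and occupy distinct
columns; their relative order within a gap interval is arbitrary.

Determinism: all randomness flows from `seed`; identical configurations
give byte-identical output, and the caller's RNG state is restored.

## What the generator does not emulate

Within-species polymorphism and coalescent discordance; recombination;
substitution-rate heterogeneity beyond the exon/intron dichotomy (no
among-site Gamma, no transition/transversion bias); alignment error (the
truth alignment is exact, whereas real pipelines inherit aligner
mistakes); PCR/cloning chimeras and sequencing error; and hexaploid or
higher formation pathways. Tests passing on simulated data therefore
validate the machinery and its statistical behaviour under the stated
model, not robustness to alignment error or to paralog contamination.

# Numerical choices and degenerate inputs

* Alignment tie-breaking is the deterministic rule of the underlying
  dynamic-programming engine; scores follow the gap cost
  $\mathrm{open} + \mathrm{extend} \cdot L$ convention.
* NJ tie-breaking: lowest (row, column) index pair; negative branch
  estimates clamped to 0 with transfer to the sister edge; matrices with
  NA/NaN, asymmetry beyond $10^{-8}$, or fewer than 3 taxa are errors.
* p-distance with zero comparable sites is an error (`hp_distance_error`),
  never silently 0; bootstrap replicates hitting this are skipped and
  counted.
* Unknown ploidy is carried as NA and simply disables the
  diploid-specific relabelling.
* Percentages are formatted to two decimals only at reporting; full
  precision is kept internally.

# Validation suite sizes

The shipped test-and-acceptance suite exercises: typing on a 36-sequence
simulated dataset with intron indels disabled (exact label recovery);
origin calls on the default conditions with 25 allo- and 25
autotetraploids and 100 bootstrap replicates (≥ 95% recovery of the true
mode, and the allopolyploid verdict provably never issued on a
monophyletic copy set); exact NJ recovery on 100 random additive matrices
(n ≤ 12) plus agreement with an independent loop-based NJ on 50 random
non-additive matrices; per-column site classification against exhaustive
counting on 200 random alignments; pseudogene detection on nine
constructed mutants; and the between-pool mean p-distance of 30
simulation replicates against the JC69 closed form within three
Monte-Carlo standard errors. These sizes were chosen to give each check
clear statistical resolution while keeping the suite quick to run on a
laptop.

# Known limitations

* The inference is per-locus: a single gene tree cannot distinguish
  allopolyploidy from ancient introgression followed by
  autopolyploidy, and incomplete lineage sorting can in principle
  mimic either pattern. The verdicts are deliberately named
  `*_PATTERN`.
* NJ on uncorrected p-distances is consistent only near additivity;
  model-corrected distances and likelihood trees are out of scope, but
  externally computed trees can be imported and fed to the inference.
* Mixed comparable-site composition under pairwise deletion can bias
  distances between sequences with large structural differences; the
  deep-split support is robust to this, but fine within-clade
  resolution near the root of a dense radiation is not to be trusted —
  one reason the separating-support definition avoids relying on it.
* Clades are anchored by exemplars; if the tree places a clade's
  exemplars non-contiguously (for example after gross misrooting), the
  assignment degrades to "unassigned" rather than guessing.
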