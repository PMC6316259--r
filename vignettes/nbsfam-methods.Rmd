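---
title: "Methods and design of nbsfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of nbsfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nbsfam implements a genome-wide characterization pipeline for plant
NBS-LRR resistance gene families. This vignette records the models and
procedures behind each stage, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical decisions taken where the underlying
methodology left choices open.

## Domain-architecture classification

NBS proteins are classified from externally produced domain calls (Pfam,
SMART, CDD, a coiled-coil predictor, or this package's own scorer) into
the eight-class vocabulary: TNL, CNL, NL, RNL, XNL, N, CN, XN. The rule is
total given three pieces of evidence — N-terminal domain (TIR / RPW8 /
CC / none), NBS presence (mandatory), LRR presence:

* TIR + NBS + LRR → TNL; RPW8 + NBS + LRR → RNL.
* CC from the coiled-coil predictor → CNL (with LRR) or CN (without).
* CC from a domain database only → XNL / XN. The "X" records that the
  evidence for a coiled coil is indirect.
* Neither → NL / N.

Predictor-positive CC evidence takes precedence over database evidence;
TIR or RPW8 together with CC resolves to the TIR/RPW8 class; TIR with
RPW8, or a missing NBS call, is a declared error rather than a silent
fallback. One choice deserves note: a criterion sometimes used to separate
"N-terminally intact" NL/XNL proteins from truncated ones (distance from
residue 1 to the NBS domain, e.g. ≥ 120 aa) is *not* part of the decision
rule here, because the eight labels are already fully determined by LRR
presence and CC evidence; adding a length parameter would create a dial
that never changes an output.

### Coiled-coil scoring

The built-in detector is a simplified Lupas-style sliding-window scorer.
Each window (14, 21 or 28 residues; default 21) is scored as the geometric
mean of per-residue heptad-position propensities from a bundled 20 × 7
table, maximized over the seven register phases. Window scores are mapped
to [0, 1] probabilities through a two-Gaussian likelihood ratio
(coiled-coil vs globular score distributions, with a weight reflecting the
rarity of coiled-coil windows). The globular means and SDs (0.90/0.14,
0.86/0.12, 0.84/0.10 for windows 14/21/28) were fitted once on per-window
score maxima of random sequences at typical globular amino-acid
composition; the coiled-coil component (mean 1.60) sits near the score of
idealized heptad repeats (≈ 1.65 under the bundled table). A residue's
score is the maximum over covering windows, and a CC call is a maximal run
of residues at or above the 0.9 probability threshold — the conventional
cutoff for this family of detectors. The scorer is deliberately *not*
claimed to be bit-compatible with the original COILS program (whose exact
matrix and weighting options are not fixed by the analysis it supports);
it serves as a boolean CC detector, and externally computed COILS calls
can be supplied through the domain table instead. Non-standard residues
receive neutral propensity 1.0.

The degenerate CC consensus (bracket syntax, e.g. `M-[KN]-D-D-…`) is
scanned literally. Hyphens are position separators; hyphens *inside*
brackets are ignored, so the typographically ambiguous fragment
`[GK][-QR]` parses as the two sets {G,K}, {Q,R} — the reading consistent
with hyphen use everywhere else in the expression.

## Physical clustering and chromosomal distribution

A cluster is a maximal run of NBS genes on one chromosome in which every
consecutive pair is < 200 kb apart with ≤ 8 annotated non-NBS genes in
between, and has ≥ 2 members. Distances are measured edge to edge (start
of the next gene minus end of the previous); the convention is not fixed
by the rule's usual statement, and edge-to-edge is the standard reading of
inter-gene distance. Maximal runs are the right construction because the
pairwise rule is transitive along a chromosome; a brute-force enumeration
oracle in the test suite checks exactly this. Genes on unanchored
scaffolds should be excluded by the caller before clustering.

Typing against a clade map: monophyletic if all assigned members share a
clade, mixed if ≥ 2 clades, untyped with < 2 assigned members. The
chi-squared test of proportionality to chromosome length uses expected
counts `total · len_i / Σ len`, k − 1 degrees of freedom and no continuity
correction; the chromosome set is exactly the names in the supplied count
vector, so a chromosome with zero NBS genes participates if (and only if)
it is passed with a zero count — the data, not the function, decides.

## Families and duplication modes

Pairwise CDS similarity uses an affine-gap local alignment (match +1,
mismatch −2, gap open 5, gap extend 2 — conventional nucleotide-BLAST-like
weights, config-exposed) with identity = matches / alignment columns and
coverage = aligned span in the longer sequence / longer length. An import
path accepts external all-vs-all BLAST tabular summaries unchanged, which
is the expected route at genome scale.

Families are single-linkage connected components over edges passing
identity > t AND coverage > t, for t in {70, 80, 90}. Single linkage is
the standard reading of pairwise family criteria; thresholds are strict
because the criteria say "> 70%". Raising t can only refine the partition
(tested property). Metrics report the percentage of genes in families of
size ≥ 2, family count, mean and maximum size.

Within-family pairs are classified: **tandem** if both members lie in one
detected cluster (tandem takes precedence when a pair would also qualify
by synteny, since cluster co-membership is the defining property of tandem
duplication); otherwise the 15 annotated genes on each side of each member
form two blocks, truncated at chromosome ends, and **segmental** requires
more than five cross-block gene pairs homologous at E < 1e-10 (that is,
≥ 6 — "more than five" read literally). Gene-level homology is consumed as
an edge list with E-values (best value per unordered pair), matching how
the synteny evidence is produced in practice (pairwise BLAST of the
blocks); the package does not recompute E-values from its own aligner.

## Promoter *cis*-element analysis

Promoters are the `upstream` bp (default 1500) immediately 5' of the
annotated gene start — taken as the translation start when the annotation
does not separate TSS and ATG — reverse-complemented for minus-strand
genes, truncated at chromosome edges, never overlapping the gene body.

Motif scanning is exact IUPAC matching, forward strand only, overlapping
matches counted. This convention matters: under it, the closed-form
expectation below reproduces the printed expected counts for the
characterized element set exactly after rounding; double-strand counting
does not. The expectation for motif length m in n sequences of length L at
G+C fraction g is `n (L − m + 1) Π_j p(class_j)` with p(G) = p(C) = g/2,
p(A) = p(T) = (1 − g)/2. Four of the ten bundled elements (GAAAAA, CAACA,
AATAGAAAA, CAATNATTG) have published expected counts that deviate from
this closed form under any single-strand i.i.d. reading (≈ 41 vs 45, ≈ 68
vs 66, ≈ 1.4 vs 2, ≈ 2.3 vs 3); the generator behind those published
values presumably used per-promoter G+C or another convention, and no
setting of this package reproduces them — they are documented rather than
fitted.

Numerical conventions, chosen once:

* Expected counts are reported rounded half-up to integers (as such tables
  print them); the float is retained internally.
* The enrichment factor divides by the *rounded* expectation — this is the
  only convention under which a motif with true expectation ≈ 0.19 and 3
  observed occurrences yields an infinite factor, as reported for the
  rarest element; 0/0 is defined as 0.
* The Monte-Carlo p-value uses the add-one (Davison–Hinkley) estimator
  (1 + #{null ≥ obs}) / (n_sets + 1), which never returns 0 and is the
  standard choice when the estimator is not otherwise specified. Control
  sets are i.i.d. per-base at the stated average G+C — no dinucleotide or
  per-promoter structure, since only the average G+C defines the null.
* Null simulation runs on integer-coded bases with vectorized class
  matching (masking windows that would cross sequence boundaries); a test
  verifies it agrees with the string scanner exactly.

Positional profiles bin match starts by upstream coordinate (−L … −1) in
100-bp bins, with a per-bin 2.5/97.5-percentile envelope from simulated
sets of matched size and composition. A 95% per-bin envelope does not give
95% *joint* coverage over 15 bins, so the envelope's calibration is tested
as aggregate per-bin coverage (≥ 93% of bin × replicate cells inside), not
as all-bins-inside-per-replicate.

## Digital expression

Hits are kept when alignment length > 100 bp and identity > 90% (strict,
so a 100-bp alignment is dropped), then reduced to one hit per read per
library with a fully deterministic tie-break — highest identity, longest
alignment, lexicographically smallest gene id — so results are a function
of the input multiset. Counts are normalized to counts-per-million; the
normalization formula behind the original "normalized counts" is not
recorded, and CPM is the simplest standard that makes the ratio threshold
meaningful across library sizes. Enrichment between two libraries uses
ratio > 8 with a pseudo-count equal to the smallest positive normalized
value (1 if all zero), which avoids infinite ratios while preserving
ranks; MA coordinates are emitted for plotting.

## The synthetic-data generator

The generator is the package's ground-truth test bed; all of its defaults
*are* the study conditions and are not tuned per test:

* Chromosome background: i.i.d. bases at 35% G+C (2 × 3 Mb by default).
* Clusters: gene "islands" separated by 250 kb (safely over the 200-kb
  rule) so the planted clusters are exactly the detectable ones; within a
  cluster, members sit at the specified edge-to-edge gaps with the
  specified number of filler genes spread inside each gap.
* Families: each tier has an ancestor CDS (480 bp); members carry copies
  with exactly `round(rate · len)` positions substituted, so the
  ancestor-member identity is analytically (1 − rate) · 100. Defaults
  plant a 5%-divergence tier (holds together through the 90% threshold)
  and a 25% tier (a family at 70% only). Member–member divergence in a
  tier is ≈ 2 · rate, which single linkage through the ancestor makes
  irrelevant to family recovery. No indels by default, keeping
  identity/coverage truth exact.
* Segmental block: a 2%-divergence copy of a tier-1 gene is placed on the
  next chromosome with 15 filler genes per side, of which 8 (default) are
  2%-mutated copies of the source's flanking fillers; those pairs are
  recorded in the emitted homology table at E = 1e-50, mirroring how
  block-synteny evidence arrives from BLAST in the real workflow.
* Promoters: 43 × 1500 bp at 35% G+C; motifs injected `floor(rate)` times
  per promoter plus a Bernoulli remainder, at a fixed upstream coordinate
  or uniformly, overwriting the background with a concrete realization of
  the IUPAC pattern; every injection is recorded.
* Hit tables: Poisson read counts per gene and library around the true
  means; a planted fraction (default 30%) of reads falls below the
  length/identity filters.

What the generator does **not** emulate: real base composition beyond
average G+C (no repeats, no transposons, no isochores), introns and
alternative transcripts (genes are single-exon, plus strand), indel
divergence (available as an option but off by default), read-mapping
ambiguity across paralogs, or overdispersed expression counts. Passing
recovery tests on this bed therefore demonstrates the correctness of the
*rules* — cluster detection, linkage, synteny counting, filtering,
thresholding — not robustness to alignment noise or annotation error in
real genomes; for real data the import paths for externally computed
domain calls, BLAST hits and mapper output are the intended route.

## Test problem sizes

The suite validates each operation against independent oracles (brute
force, enumeration, closed form) and the planted truth: 100 seeded random
instances each for motif scanning, single-linkage family construction and
cluster detection; 20 seeded genome replicates for end-to-end recovery of
cluster memberships, family tiers and duplication modes (≥ 95% of planted
labels); Monte-Carlo calibration at 2000 control sets per motif with the
null mean required within 3 standard errors of the closed form, and a
type-I check of the empirical test over 1000 background-only promoter sets
(rejection at α = 0.05 within 0.05 ± 0.02); chi-squared calibration over
10,000 proportional-sampling replicates. These sizes keep each property at
tight statistical resolution while the whole suite stays comfortably
interactive.

## Known limitations

* The coiled-coil scorer is a calibrated re-implementation, not COILS;
  borderline proteins may be called differently than by the original
  program. Supplying precomputed predictor calls sidesteps this entirely.
* Identity/coverage from the built-in aligner correspond to the single
  best local alignment; workflows that sum multiple HSPs per pair will
  differ for highly rearranged genes. The import path accepts whichever
  convention produced the table.
* Promoter extraction anchors at the annotated gene start; annotations
  with separate TSS features are not interpreted specially.
* The expression stage is summarization plus thresholding, not
  differential-expression inference: no dispersion modeling, no
  replication structure.
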