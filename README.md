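# nbsfam

Genome-wide analysis of plant **NBS-LRR disease-resistance gene families**
in R. The package is aimed at plant genomicists characterizing the
resistance (R) gene repertoire of a newly assembled genome: it turns a
genome + annotation + per-protein domain calls into the standard set of
gene-family results — architecture classes, physical clusters, duplication
history, promoter *cis*-element enrichment, and digital expression — with
every stage testable against synthetic data of known structure.

## What it computes

**Domain architecture.** Each NBS protein is placed in one of the eight
standard classes (TNL, CNL, NL, RNL, XNL, N, CN, XN) from its TIR / CC /
NBS / LRR / RPW8 domain calls, with coiled-coil evidence from either a
bundled Lupas-style sliding-window scorer (heptad propensities, geometric
mean over register phases, two-Gaussian likelihood ratio, call threshold
0.9) or precomputed predictor output, and a degenerate-consensus scanner
for the CC N-terminal signature.

**Physical clusters.** A cluster is a maximal run of NBS genes in which
consecutive genes are < 200 kb apart (edge to edge) with ≤ 8 annotated
genes between them. Clusters are typed monophyletic/mixed against a clade
map, and a chi-squared test (expected counts proportional to chromosome
length, k−1 df) assesses chromosomal enrichment.

**Duplication analysis.** All-vs-all CDS similarities (affine-gap local
alignment; or imported BLAST tabular hits) feed single-linkage multigene
families at identity-and-coverage-of-longer-gene thresholds of 70/80/90%.
Within-family pairs are **tandem** when they share a cluster; otherwise the
15 flanking genes on each side of each member are compared, and > 5
homologous cross-block pairs (E < 1e-10) make the pair **segmental**.

**Promoter *cis*-elements.** 1500-bp promoters upstream of the gene start
are scanned for IUPAC motifs (forward strand, overlapping matches). The
expected count for a motif of length m in n promoters of length L at G+C
fraction g is

    E = n · (L − m + 1) · Π_j p(class_j),   p(G)=p(C)=g/2, p(A)=p(T)=(1−g)/2

and significance comes from a Monte-Carlo null (2000 control sets of
matched size, length and G+C; add-one empirical p-value). Enrichment
factors divide observed counts by the *rounded* expectation; positional
bias is profiled in 100-bp bins against a simulated envelope.

**Digital expression.** Read-mapping hit tables are filtered (> 100 bp,
> 90% identity, one hit per read), counted per gene and library,
normalized to counts-per-million, and genes with a count ratio > 8 between
two libraries are called tissue-enriched.

**Synthetic data.** `simulation_recipe()` / `simulate_genome()` /
`simulate_promoters()` / `simulate_hits()` plant clusters, divergence-tier
families, a segmental block, promoter motifs and expression signal with
exact ground truth, so every stage above is validated by parameter
recovery.

## Worked example

```r
library(nbsfam)

rec  <- simulation_recipe(seed = 42)
sim  <- simulate_genome(rec)
nbs  <- sim$genes[sim$genes$gene_id %in% sim$nbs_ids, ]

clusters <- detect_clusters(nbs, sim$genes)
cluster_summary(clusters, n_mapped = nrow(nbs))$per_cluster
#>   cluster_id chromosome n_members span_kb n_intervening
#> 1          1       chr1         3 101.433             4
#> 2          2       chr1         2  30.958             0

pairs <- all_vs_all_similarity(setNames(nbs$cds, nbs$gene_id))
threshold_sweep(pairs, nbs$gene_id)$metrics
#>  threshold pct_in_families n_families max_size mean_size
#>         70        77.77778          2        5       3.5
#>         80        55.55556          1        5       5.0
#>         90        55.55556          1        5       5.0
```

The two planted clusters are recovered exactly; the 25%-divergence family
dissolves between the 70% and 80% thresholds while the 5%-divergence
family (including its segmental copy) survives at 90%. Duplication
classification on the same run yields 3 tandem, 1 segmental and 7
unclassified within-family pairs, matching the planted truth.

```r
prec <- simulation_recipe(seed = 42, planted_motifs = list(
  list(name = "RAV1AAT", iupac = "CAACA", rate = 2, position = NULL)))
sp  <- simulate_promoters(prec)
motif_enrichment(sp$promoters,
                 subset(default_motifs(), name %in% c("RAV1AAT", "MYCATERD22")),
                 gc = 0.35, n_sets = 2000, seed = 1)
#>        name n_promoters_with_hit n_occurrences expected_rounded enrichment_factor p_value
#>  MYCATERD22                   17            21               12              1.75  0.0115
#>     RAV1AAT                   43           157               68              2.31  0.0005
```

RAV1AAT was planted at 2 copies per promoter on top of the ~68 background
occurrences expected at 35% G+C, and the Monte-Carlo test flags it
(p ≈ 5e-4); MYCATERD22 shows only its background-level weak signal.

A full pipeline over files (GFF3 + FASTA + domain TSV + optional clade
map, homology table and hit table) is `run_pipeline(config, out_dir)`; a
thin command-line wrapper lives in `inst/cli/nbsfam.R`.

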