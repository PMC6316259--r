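test_that("pairwise similarity summarizes local alignments like BLAST output", {
  set.seed(31)
  s <- random_dna_str(300)
  same <- pairwise_similarity(s, s)
  expect_equal(same$pct_identity, 100)
  expect_equal(same$pct_coverage, 100)

  # 30 substitutions planted away from the ends: identity ~90, coverage ~100
  v <- strsplit(s, "")[[1]]
  pos <- sample(6:295, 30)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  mut <- paste(v, collapse = "")
  res <- pairwise_similarity(s, mut)
  expect_gte(res$pct_identity, 89)
  expect_lte(res$pct_identity, 91)
  expect_gte(res$pct_coverage, 98)

  expect_error(pairwise_similarity("ACGU", "ACGT"), "non-ACGTN")
  expect_error(pairwise_similarity("", "ACGT"), "empty")
})

test_that("unrelated random sequences rarely reach the 70% coverage bar", {
  set.seed(32)
  low <- replicate(100, {
    pairwise_similarity(random_dna_str(300), random_dna_str(300))$pct_coverage
  })
  expect_gte(mean(low < 70), 0.95)
})

test_that("family construction is single-linkage over passing edges", {
  pairs <- data.frame(
    gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"),
    pct_identity = c(95, 95, 10), pct_coverage = c(95, 95, 10),
    stringsAsFactors = FALSE)
  fs <- build_families(pairs, c("a", "b", "c"), 70)
  expect_equal(fs$families, list(c("a", "b", "c")))
  expect_length(fs$singletons, 0)

  none <- build_families(pairs, c("a", "b", "c"), 99)
  expect_length(none$families, 0)
  expect_equal(none$singletons, c("a", "b", "c"))

  expect_error(build_families(pairs, c("a", "b"), 70), "unknown gene")
})

test_that("families match the transitive-closure oracle on random instances", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    genes <- sprintf("g%02d", 1:n)
    npairs <- sample(1:40, 1)
    pairs <- data.frame(
      gene_a = sample(genes, npairs, replace = TRUE),
      gene_b = sample(genes, npairs, replace = TRUE),
      pct_identity = runif(npairs, 0, 100),
      pct_coverage = runif(npairs, 0, 100), stringsAsFactors = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    thr <- sample(c(50, 70, 90), 1)
    got <- build_families(pairs, genes, thr)
    want <- oracle_families(pairs, genes, thr)
    got_sorted <- got$families[order(vapply(got$families, `[`, "", 1))]
    want_sorted <- want$families[order(vapply(want$families, `[`, "", 1))]
    expect_equal(got_sorted, want_sorted)
    expect_equal(got$singletons, want$singletons)
  }
})

test_that("raising the threshold only refines the family partition", {
  set.seed(34)
  genes <- sprintf("g%02d", 1:20)
  pairs <- expand.grid(gene_a = genes, gene_b = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene_a < pairs$gene_b, ]
  pairs$pct_identity <- runif(nrow(pairs), 40, 100)
  pairs$pct_coverage <- runif(nrow(pairs), 40, 100)
  sw <- threshold_sweep(pairs, genes, thresholds = c(70, 80, 90))
  for (hi in c("80", "90")) {
    for (fam in sw$family_sets[[hi]]$families) {
      parents <- vapply(sw$family_sets[["70"]]$families,
                        function(f) all(fam %in% f), logical(1))
      expect_equal(sum(parents), 1)
    }
  }
  single <- threshold_sweep(pairs, genes, thresholds = 80)
  direct <- build_families(pairs, genes, 80)
  expect_equal(single$family_sets[["80"]]$families, direct$families)
})

test_that("family metrics do the printed-count arithmetic", {
  fs <- structure(list(threshold = 70,
                       families = list(sprintf("a%d", 1:19),
                                       sprintf("b%d", 1:5),
                                       sprintf("c%d", 1:3),
                                       sprintf("d%d", 1:2),
                                       sprintf("e%d", 1:1)),
                       singletons = character(0)), class = "family_set")
  # 19+5+3+2+1 = 30 genes in 5 families of a 49-gene set
  m <- family_metrics(fs, 49)
  expect_equal(round(m$pct_in_families, 1), 61.2)
  expect_equal(m$mean_size, 6)
  expect_equal(round(m$largest_family_share), 63)

  two <- structure(list(threshold = 70, families = list(c("a", "b")),
                        singletons = character(0)), class = "family_set")
  m2 <- family_metrics(two, 2)
  expect_equal(m2$pct_in_families, 100)
  expect_equal(m2$mean_size, 2)

  empty <- structure(list(threshold = 70, families = list(),
                          singletons = c("a")), class = "family_set")
  m3 <- family_metrics(empty, 1)
  expect_equal(m3$mean_size, 0)
  expect_false(m3$mean_defined)
})

test_that("duplicate pairs split into tandem, segmental and unclassified", {
  # one cluster holding a family pair -> tandem
  lay <- make_layout(c("n1", "n2", "n3"), c(1000, 11000, 900000),
                     c(1999, 11999, 900999))
  clusters <- detect_clusters(lay, lay)
  fs <- structure(list(threshold = 70, families = list(c("n1", "n2")),
                       singletons = "n3"), class = "family_set")
  hom <- data.frame(gene_a = character(0), gene_b = character(0),
                    evalue = numeric(0))
  d <- classify_duplications(fs, clusters, lay, hom)
  expect_equal(d$mode, "tandem")

  # family pair on different chromosomes with no flanking homology
  lay2 <- rbind(make_layout(c("n1"), 50000, 50999),
                make_layout(c("n2"), 50000, 50999, chromosome = "chr2"))
  fs2 <- structure(list(threshold = 70, families = list(c("n1", "n2")),
                        singletons = character(0)), class = "family_set")
  d2 <- classify_duplications(fs2, clusters[0, ], lay2, hom)
  expect_equal(d2$mode, "unclassified")
  expect_equal(d2$n_syntenic_pairs, 0L)

  expect_error(classify_duplications(fs2, clusters[0, ], lay2, hom,
                                     flank = 0), "flank")
})

test_that("a planted duplicated block with 8 flank homologs is segmental", {
  # chr1: 8 fillers, n1, 8 fillers; chr2 copies the block
  f1 <- sprintf("f%02d", 1:16)
  f2 <- sprintf("h%02d", 1:16)
  starts <- (1:17) * 10000
  lay <- rbind(
    make_layout(c(f1[1:8], "n1", f1[9:16]), starts, starts + 999),
    make_layout(c(f2[1:8], "n2", f2[9:16]), starts, starts + 999,
                chromosome = "chr2"))
  fs <- structure(list(threshold = 70, families = list(c("n1", "n2")),
                       singletons = character(0)), class = "family_set")
  hom <- data.frame(gene_a = c(f1[5:8], f1[9:12]),
                    gene_b = c(f2[5:8], f2[9:12]),
                    evalue = 1e-50, stringsAsFactors = FALSE)
  d <- classify_duplications(fs, detect_clusters(lay[0, ], lay), lay, hom)
  expect_equal(d$mode, "segmental")
  expect_equal(d$n_syntenic_pairs, 8L)

  # exactly 5 homolog pairs is not "more than five"
  d5 <- classify_duplications(fs, detect_clusters(lay[0, ], lay), lay,
                              hom[1:5, ])
  expect_equal(d5$mode, "unclassified")

  # weak evalues do not count
  hom_weak <- hom
  hom_weak$evalue <- 1e-5
  dw <- classify_duplications(fs, detect_clusters(lay[0, ], lay), lay,
                              hom_weak)
  expect_equal(dw$mode, "unclassified")
})

test_that("no pair is both tandem and segmental and tandem implies one chromosome", {
  set.seed(36)
  sim <- simulate_genome(simulation_recipe(seed = 36))
  nbs <- sim$genes[sim$genes$gene_id %in% sim$nbs_ids, ]
  clusters <- detect_clusters(nbs, sim$genes)
  pairs <- all_vs_all_similarity(setNames(nbs$cds, nbs$gene_id))
  fs <- build_families(pairs, nbs$gene_id, 70)
  d <- classify_duplications(fs, clusters, sim$genes, sim$homology)
  expect_equal(anyDuplicated(d[, c("gene_a", "gene_b")]), 0)
  tandem <- d[d$mode == "tandem", ]
  for (i in seq_len(nrow(tandem))) {
    chr_a <- nbs$chromosome[nbs$gene_id == tandem$gene_a[i]]
    chr_b <- nbs$chromosome[nbs$gene_id == tandem$gene_b[i]]
    expect_equal(chr_a, chr_b)
  }
})
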