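test_that("promoters are the upstream slice on either strand", {
  set.seed(41)
  chr <- random_dna_str(3000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  plus <- make_gene_row("gp", "chr1", 2001, 2600)
  ps <- extract_promoters(genome, plus, upstream = 1500)
  expect_equal(unname(ps$sequences["gp"]), substr(chr, 501, 2000))

  minus <- make_gene_row("gm", "chr1", 500, 1000, strand = "-")
  psm <- extract_promoters(genome, minus, upstream = 1500)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 1001, 2500))))
  expect_equal(unname(psm$sequences["gm"]), rc)

  # truncation at the chromosome start, and an empty-promoter warning at 1
  near <- make_gene_row("gn", "chr1", 301, 900)
  expect_equal(nchar(extract_promoters(genome, near)$sequences[["gn"]]), 300)
  at1 <- make_gene_row("g0", "chr1", 1, 600)
  expect_warning(ps0 <- extract_promoters(genome, rbind(at1, plus)),
                 "empty promoter")
  expect_equal(nchar(ps0$sequences[["g0"]]), 0)
})

test_that("promoter extraction respects exclusions and gene bodies", {
  set.seed(42)
  chr <- random_dna_str(120000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  genes <- make_layout(sprintf("g%02d", 1:48), (1:48) * 2400 + 2000,
                       (1:48) * 2400 + 2300)
  excl <- sprintf("g%02d", c(3, 9, 20, 31, 44))
  ps <- extract_promoters(genome, genes, upstream = 1500, exclude = excl)
  expect_length(ps$sequences, 43)
  expect_false(any(excl %in% names(ps$sequences)))

  # the promoter never contains a base of its own gene body
  g <- genes[1, ]
  prom <- ps$sequences[[g$gene_id]]
  expect_equal(prom,
               substr(chr, g$start - nchar(prom), g$start - 1))
})

test_that("motif scanning matches the brute-force oracle", {
  expect_equal(scan_motif("CAACAACA", "CAACA"), c(1, 4))
  expect_equal(scan_motif("TTTGACC", "TTTGACY"), 1)
  expect_equal(scan_motif("TTTGACT", "TTTGACY"), 1)
  expect_equal(scan_motif("TTTGACA", "TTTGACY"), integer(0))
  expect_equal(scan_motif("ACG", "ACGTT"), integer(0))

  set.seed(43)
  motifs <- c("CAACA", "TTTGACY", "CAATNATTG", "ACGTGTC", "SWKM")
  for (rep in 1:100) {
    seq <- random_dna_str(sample(20:2000, 1), gc = runif(1, 0.25, 0.6))
    m <- sample(motifs, 1)
    expect_equal(scan_motif(seq, m), oracle_scan(seq, m))
  }
})

test_that("expected counts follow the closed-form background model", {
  expect_equal(expected_count("CACATG"), 11.827, tolerance = 1e-4)
  expect_equal(expected_count("CACCTG"), 6.3684, tolerance = 1e-4)
  # a single N position is certain: expectation is every position
  expect_equal(expected_count("N", n_seqs = 10, seq_len = 100), 1000)
  expect_error(expected_count("CAAXA"), "non-IUPAC")
})

test_that("the Monte-Carlo null is centered on the closed form and deterministic", {
  mc <- monte_carlo_null("CACATG", observed = 23, n_sets = 300, seed = 7)
  se <- mc$null_sd / sqrt(300)
  expect_lt(abs(mc$null_mean - expected_count("CACATG")), 3 * se)

  mc0 <- monte_carlo_null("CACATG", observed = 0, n_sets = 100, seed = 7)
  expect_equal(mc0$p_value, 1)

  again <- monte_carlo_null("CACATG", observed = 23, n_sets = 300, seed = 7)
  expect_identical(mc$null_counts, again$null_counts)
  expect_identical(mc$p_value, again$p_value)

  # p is anti-monotone in the observed count for a fixed null
  p_lo <- (1 + sum(mc$null_counts >= 10)) / 301
  p_hi <- (1 + sum(mc$null_counts >= 25)) / 301
  expect_gte(p_lo, p_hi)
})

test_that("the integer-coded null counter agrees with the string scanner", {
  # decode one simulated set and recount with scan_motif
  set.seed(8)
  n_sets <- 3; set_n <- 5; L <- 400
  counts <- nbsfam:::simulate_null_counts("CAACA", n_sets, set_n, L,
                                          gc = 0.35, seed = 99)
  set.seed(99)
  pb <- c(A = 0.325, C = 0.175, G = 0.175, T = 0.325)
  for (s in 1:n_sets) {
    bases <- sample.int(4, set_n * L, replace = TRUE, prob = pb)
    seqs <- vapply(seq_len(set_n), function(i) {
      paste(c("A", "C", "G", "T")[bases[((i - 1) * L + 1):(i * L)]],
            collapse = "")
    }, character(1))
    expect_equal(sum(vapply(seqs, function(x)
      length(scan_motif(x, "CAACA")), integer(1))),
      unname(counts[s, 1]))
  }
})

test_that("enrichment factors divide by the rounded expectation", {
  expect_equal(round(enrichment_factor(94, 66.4), 1), 1.4)
  expect_equal(enrichment_factor(15, 3.2), 5)
  expect_equal(enrichment_factor(3, 0.19), Inf)
  expect_equal(enrichment_factor(0, 0.19), 0)
  expect_equal(enrichment_factor(12, 6.4), 2)
})

test_that("positional profiles bin matches by upstream coordinate", {
  # all matches planted at -550 fall in the [-600, -501] bin
  rec <- simulation_recipe(seed = 44, planted_motifs = list(
    list(name = "MYC", iupac = "CACATG", rate = 1.0, position = -550)))
  sp <- simulate_promoters(rec)
  pp <- positional_profile(sp$promoters, "CACATG", n_sims = 20, seed = 2)
  peak <- pp[which.max(pp$count), ]
  expect_equal(peak$bin_start, -600)
  expect_gte(peak$count, 40)

  # conservation: bin counts sum to the scan total
  expect_equal(sum(pp$count),
               sum(vapply(sp$promoters$sequences, function(s)
                 length(scan_motif(s, "CACATG")), integer(1))))
  expect_error(positional_profile(sp$promoters, "CACATG", bin_width = 37),
               "divide")
})

test_that("the simulation envelope covers background-only bin counts", {
  set.seed(45)
  inside <- 0; total <- 0
  for (rep in 1:15) {
    rec <- simulation_recipe(seed = 4500 + rep)
    sp <- simulate_promoters(rec)
    pp <- positional_profile(sp$promoters, "CACATG", n_sims = 100,
                             seed = 4600 + rep)
    inside <- inside + sum(pp$count >= pp$env_low & pp$count <= pp$env_high)
    total <- total + nrow(pp)
  }
  expect_gte(inside / total, 0.93)
})

test_that("G+C content pools counts and reports the per-sequence range", {
  ps <- promoter_set(c(a = "GGCC", b = "ATGC"), target_length = 10)
  gc <- gc_content(ps)
  expect_equal(gc$pooled, 6 / 8)
  expect_equal(gc$per_sequence_range, c(0.5, 1))
  expect_equal(gc_content(promoter_set(c(a = "GGCC")))$pooled, 1)

  set.seed(46)
  big <- promoter_set(setNames(replicate(43, random_dna_str(1500, gc = 0.35)),
                               sprintf("p%02d", 1:43)))
  expect_lt(abs(big$gc_content - 0.35), 0.01)

  # the constructor pools G+C itself, warning on all-ambiguous sequences
  expect_warning(promoter_set(c(a = "NNNN", b = "ATGC"), target_length = 10),
                 "excluded")
})
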