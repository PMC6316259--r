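dom <- function(gene_id, domain, source, start = 1, end = 50) {
  data.frame(gene_id = gene_id, domain = domain, start = start, end = end,
             source = source, score = 1, stringsAsFactors = FALSE)
}

arch_of <- function(...) classify_architecture(do.call(rbind, list(...)))

test_that("architecture classification follows the eight-class scheme", {
  expect_equal(arch_of(dom("g", "CC", "COILS"), dom("g", "NBS", "CDD"),
                       dom("g", "LRR", "PFAM")), "CNL")
  expect_equal(arch_of(dom("g", "NBS", "CDD")), "N")
  # CC seen only by the domain database, not the coiled-coil predictor
  expect_equal(arch_of(dom("g", "CC", "CDD"), dom("g", "NBS", "CDD"),
                       dom("g", "LRR", "PFAM")), "XNL")
  expect_equal(arch_of(dom("g", "NBS", "CDD"), dom("g", "LRR", "PFAM")), "NL")
  expect_equal(arch_of(dom("g", "RPW8", "PFAM"), dom("g", "NBS", "CDD"),
                       dom("g", "LRR", "PFAM")), "RNL")
  expect_equal(arch_of(dom("g", "TIR", "PFAM"), dom("g", "NBS", "CDD"),
                       dom("g", "LRR", "PFAM")), "TNL")
  expect_equal(arch_of(dom("g", "CC", "COILS"), dom("g", "NBS", "CDD")), "CN")
  expect_equal(arch_of(dom("g", "CC", "CDD"), dom("g", "NBS", "CDD")), "XN")
  # predictor evidence dominates database evidence
  expect_equal(arch_of(dom("g", "CC", "COILS"), dom("g", "CC", "CDD"),
                       dom("g", "NBS", "CDD"), dom("g", "LRR", "PFAM")), "CNL")
})

test_that("non-NBS and contradictory architectures are declared errors", {
  expect_error(arch_of(dom("g", "LRR", "PFAM")), "not an NBS gene")
  expect_error(arch_of(dom("g", "TIR", "PFAM"), dom("g", "RPW8", "PFAM"),
                       dom("g", "NBS", "CDD"), dom("g", "LRR", "PFAM")),
               "contradictory")
})

test_that("every evidence combination maps to one label or a declared error", {
  combos <- expand.grid(tir = c(FALSE, TRUE), rpw8 = c(FALSE, TRUE),
                        cc = c("none", "coils", "cdd"),
                        lrr = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    calls <- list(dom("g", "NBS", "CDD"))
    if (combos$tir[i]) calls <- c(calls, list(dom("g", "TIR", "PFAM")))
    if (combos$rpw8[i]) calls <- c(calls, list(dom("g", "RPW8", "PFAM")))
    if (combos$cc[i] == "coils") calls <- c(calls, list(dom("g", "CC", "COILS")))
    if (combos$cc[i] == "cdd") calls <- c(calls, list(dom("g", "CC", "CDD")))
    if (combos$lrr[i]) calls <- c(calls, list(dom("g", "LRR", "PFAM")))
    res <- tryCatch(classify_architecture(do.call(rbind, calls)),
                    error = function(e) "ERROR")
    expect_true(res %in% c("TNL", "CNL", "NL", "RNL", "XNL", "N", "CN", "XN",
                           "ERROR"))
  }
})

test_that("class summaries count each label and are permutation invariant", {
  labels <- c(rep("CNL", 29), rep("NL", 6), rep("RNL", 4), rep("XNL", 3),
              rep("N", 4), rep("CN", 2), "XN")
  tab <- summarize_classes(labels)
  expect_equal(unname(tab["CNL"]), 29L)
  expect_equal(unname(tab["total"]), 49L)
  expect_equal(unname(tab["TNL"]), 0L)
  set.seed(3)
  expect_identical(summarize_classes(sample(labels)), tab)
  empty <- summarize_classes(character(0))
  expect_true(all(empty == 0))
})

test_that("variant summaries do the locus/model arithmetic", {
  g <- do.call(rbind, c(
    lapply(1:42, function(i) make_gene_row(paste0("s", i), "chr1", i * 10,
                                           i * 10 + 5)),
    Map(function(i, v) make_gene_row(paste0("m", i), "chr2", i * 10,
                                     i * 10 + 5, n_variants = v),
        1:6, c(2L, 3L, 3L, 3L, 5L, 7L))))
  vs <- variant_summary(g)
  expect_equal(vs$n_loci, 48)
  expect_equal(vs$n_multi_variant_loci, 6)
  expect_equal(vs$n_models, 42 + 23)

  g49 <- do.call(rbind, lapply(1:49, function(i)
    make_gene_row(paste0("g", i), "chr1", i * 10, i * 10 + 5,
                  n_variants = if (i <= 7) 2L else 1L)))
  expect_equal(variant_summary(g49)$fraction_multi, 7 / 49)

  single <- make_gene_row("g1", "chr1", 1, 10)
  expect_equal(variant_summary(single)$fraction_multi, 0)
})

test_that("consensus pattern scanning matches a brute-force check", {
  core <- "MKDDLQRRKDALPRIQAVVEAAESGQQEIT"
  set.seed(11)
  prot <- paste0(random_protein(30), core, random_protein(40))
  expect_equal(scan_cc_consensus(prot), 31)

  expect_equal(scan_cc_consensus("AMA", "[M]"), 2)
  expect_equal(scan_cc_consensus("AAAA", "[KR]"), integer(0))
  expect_error(parse_aa_pattern("A-[]-B"), "empty alternative")

  # oracle equivalence on random proteins against a simple position scan
  pat <- "M-[KN]-D-[DE]"
  sets <- parse_aa_pattern(pat)
  set.seed(12)
  for (rep in 1:25) {
    prot <- random_protein(sample(10:200, 1))
    aa <- strsplit(prot, "")[[1]]
    brute <- integer(0)
    for (i in seq_len(max(length(aa) - length(sets) + 1, 0))) {
      if (all(mapply(function(s, j) aa[i + j - 1] %in% s, sets,
                     seq_along(sets)))) {
        brute <- c(brute, i)
      }
    }
    expect_equal(scan_cc_consensus(prot, pat), brute)
  }
})

test_that("the bracket pattern parser treats hyphens as separators only", {
  sets <- parse_aa_pattern("[GK][-QR]")
  expect_equal(sets, list(c("G", "K"), c("Q", "R")))
  expect_length(parse_aa_pattern(cc_consensus_pattern()), 30)
})

test_that("coiled-coil scoring separates heptad repeats from controls", {
  ideal <- paste(rep("LEALEGK", 8), collapse = "")
  prof <- coiled_coil_score(ideal, window = 21)
  expect_gte(max(prof$per_residue_score), 0.9)
  expect_gte(nrow(prof$calls), 1)

  polyp <- paste(rep("P", 28), collapse = "")
  expect_lt(max(coiled_coil_score(polyp, window = 21)$per_residue_score), 0.9)

  expect_error(coiled_coil_score("LEALEGK", window = 21), "shorter")
  expect_error(coiled_coil_score(ideal, window = 10), "window")

  # scores are local: residues far from appended tail are unchanged
  ext <- paste0(ideal, paste(rep("G", 30), collapse = ""))
  a <- coiled_coil_score(ideal, window = 21)$per_residue_score[1:30]
  b <- coiled_coil_score(ext, window = 21)$per_residue_score[1:30]
  expect_equal(a, b)

  # random proteins are not called at the 0.9 threshold
  set.seed(21)
  for (i in 1:10) {
    p <- coiled_coil_score(random_protein(200), window = 21)
    expect_lt(max(p$per_residue_score), 0.9)
  }
})
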