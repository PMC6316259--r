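# Shared fixture builders; everything is generated in code at test time.

make_gene_row <- function(gene_id, chromosome, start, end, strand = "+",
                          n_variants = 1L, cds = "", protein = NA_character_) {
  data.frame(gene_id = gene_id, chromosome = chromosome, start = start,
             end = end, strand = strand, n_variants = n_variants,
             cds = cds, protein = protein, stringsAsFactors = FALSE)
}

# A gene layout on one chromosome from (id, start, end) triples.
make_layout <- function(ids, starts, ends, chromosome = "chr1") {
  do.call(rbind, Map(function(i, s, e)
    make_gene_row(i, chromosome, s, e), ids, starts, ends))
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

random_dna_str <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

# Brute-force oracle: scan a DNA sequence for an IUPAC motif position by
# position using the raw code map.
oracle_scan <- function(seq, motif) {
  classes <- lapply(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]],
                    function(s) strsplit(s, "")[[1]])
  v <- strsplit(seq, "")[[1]]
  m <- length(classes)
  if (length(v) < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(length(v) - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(v[i + j - 1] %in% classes[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Brute-force oracle: transitive closure of passing edges.
oracle_families <- function(pairs, genes, threshold) {
  adj <- matrix(FALSE, length(genes), length(genes),
                dimnames = list(genes, genes))
  keep <- pairs$pct_identity > threshold & pairs$pct_coverage > threshold
  for (k in which(keep)) {
    adj[pairs$gene_a[k], pairs$gene_b[k]] <- TRUE
    adj[pairs$gene_b[k], pairs$gene_a[k]] <- TRUE
  }
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(r) paste(sort(genes[r]),
                                                  collapse = ",")))
  comps <- lapply(strsplit(comps, ","), sort)
  singl <- unlist(comps[lengths(comps) == 1])
  if (is.null(singl)) singl <- character(0)
  list(families = comps[lengths(comps) >= 2],
       singletons = sort(as.character(singl)))
}

# Brute-force oracle: all maximal runs of NBS genes satisfying the pairwise
# gap / intervening rule, by direct enumeration of candidate runs.
oracle_clusters <- function(nbs, all_genes, max_gap_kb = 200,
                            max_intervening = 8, min_size = 2) {
  out <- list()
  for (chr in unique(nbs$chromosome)) {
    sub <- nbs[nbs$chromosome == chr, ]
    sub <- sub[order(sub$start), ]
    oth <- all_genes[all_genes$chromosome == chr &
                       !(all_genes$gene_id %in% nbs$gene_id), ]
    n <- nrow(sub)
    pair_ok <- function(i) {
      gap <- (sub$start[i + 1] - sub$end[i]) / 1000
      nb <- sum(oth$start > sub$end[i] & oth$end < sub$start[i + 1])
      gap < max_gap_kb && nb <= max_intervening
    }
    runs <- list()
    for (a in seq_len(n)) for (b in a:n) {
      ok <- all(vapply(seq_len(max(b - a, 0)) + a - 1, pair_ok, logical(1)))
      if (ok) runs[[length(runs) + 1]] <- c(a, b)
    }
    # maximal runs only
    for (r in runs) {
      is_max <- !any(vapply(runs, function(q)
        (q[1] < r[1] && q[2] >= r[2]) || (q[1] <= r[1] && q[2] > r[2]),
        logical(1)))
      if (is_max && r[2] - r[1] + 1 >= min_size) {
        out[[length(out) + 1]] <- sub$gene_id[r[1]:r[2]]
      }
    }
  }
  out
}
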