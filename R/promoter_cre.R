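#' Built-in cis-regulatory element motif set
#'
#' The ten stress- and defense-associated plant promoter elements used
#' throughout the promoter analysis, as name + IUPAC pairs (e.g.
#' WBBOXPCWRKY1 = TTTGACY, RAV1AAT = CAACA). The sucrose-responsive element
#' is shipped under both reported spellings (AATAGAAAA and AATACAAAA, the
#' latter flagged as a variant); ABRE/ABR name the same ACGTGTC element.
#'
#' @return Data.frame with columns `name`, `iupac`, `note`.
#' @export
default_motifs <- function() {
  path <- system.file("extdata", "cre_motifs.tsv", package = "nbsfam")
  read.delim(path, stringsAsFactors = FALSE)
}

validate_motif <- function(iupac) {
  if (nchar(iupac) < 1) stop("empty motif", call. = FALSE)
  bad <- setdiff(strsplit(toupper(iupac), "")[[1]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) stop("motif contains non-IUPAC letter(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  toupper(iupac)
}

#' Extract promoter sequences upstream of gene starts
#'
#' For a plus-strand gene the promoter is the `upstream` bp immediately 5'
#' of the annotated gene start (assumed to be the ATG); for a minus-strand
#' gene, the reverse complement of the bp immediately 3' of the gene end.
#' Promoters are truncated at chromosome edges (with a warning when empty),
#' never overlap the gene's own body, and genes in `exclude` (e.g. flagged
#' for coding-sequence overlap) are omitted.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param genes Gene-model data.frame.
#' @param upstream Promoter length in bp (default 1500).
#' @param exclude Character vector of gene ids to drop.
#' @return A `promoter_set`: list with `sequences` (named character vector,
#'   gene_id -> promoter, written 5'->3' toward the gene start),
#'   `target_length` and `gc_content` (pooled G+C fraction).
#' @export
extract_promoters <- function(genome, genes, upstream = 1500,
                              exclude = character(0)) {
  keep <- genes[!(genes$gene_id %in% exclude), , drop = FALSE]
  miss <- setdiff(unique(keep$chromosome), names(genome))
  if (length(miss) > 0) stop("chromosome(s) absent from genome: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  seqs <- character(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    g <- keep[i, ]
    chr_len <- Biostrings::width(genome)[match(g$chromosome, names(genome))]
    if (g$strand == "+") {
      from <- max(1, g$start - upstream)
      to <- g$start - 1
      if (to < from) {
        warning(g$gene_id, ": gene at chromosome start; empty promoter")
        seqs[i] <- ""
        next
      }
      seqs[i] <- as.character(Biostrings::subseq(genome[[g$chromosome]],
                                                 from, to))
    } else {
      from <- g$end + 1
      to <- min(chr_len, g$end + upstream)
      if (to < from) {
        warning(g$gene_id, ": gene at chromosome end; empty promoter")
        seqs[i] <- ""
        next
      }
      s <- Biostrings::subseq(genome[[g$chromosome]], from, to)
      seqs[i] <- as.character(Biostrings::reverseComplement(s))
    }
  }
  names(seqs) <- keep$gene_id
  promoter_set(seqs, target_length = upstream)
}

#' Construct a promoter set
#'
#' @param sequences Named character vector of promoter sequences.
#' @param target_length Nominal promoter length in bp (default 1500).
#' @return A `promoter_set` with pooled `gc_content` computed.
#' @export
promoter_set <- function(sequences, target_length = 1500) {
  if (any(nchar(sequences) > target_length)) {
    stop("promoter longer than target_length", call. = FALSE)
  }
  ps <- structure(list(sequences = sequences, target_length = target_length,
                       gc_content = NA_real_), class = "promoter_set")
  ps$gc_content <- gc_content(ps)$pooled
  ps
}

#' G+C content of a promoter set
#'
#' @param promoters A `promoter_set`.
#' @return List with `pooled` ((G+C)/(A+C+G+T) over all sequences) and
#'   `per_sequence_range` (min/max of per-sequence fractions). Sequences
#'   with no unambiguous base are excluded with a warning.
#' @export
gc_content <- function(promoters) {
  seqs <- promoters$sequences
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) stop("empty promoter set", call. = FALSE)
  counts <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    c(gc = sum(v %in% c("G", "C")), acgt = sum(v %in% c("A", "C", "G", "T")))
  }, numeric(2))
  usable <- counts["acgt", ] > 0
  if (!all(usable)) {
    warning(sum(!usable), " all-ambiguous sequence(s) excluded from G+C")
    counts <- counts[, usable, drop = FALSE]
  }
  per_seq <- counts["gc", ] / counts["acgt", ]
  list(pooled = sum(counts["gc", ]) / sum(counts["acgt", ]),
       per_sequence_range = range(per_seq))
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports every 1-based start position where each sequence base falls in
#' the corresponding IUPAC class. Overlapping matches are counted; only the
#' forward strand is scanned.
#'
#' @param seq DNA string.
#' @param motif IUPAC motif string.
#' @return Integer vector of match start positions.
#' @export
scan_motif <- function(seq, motif) {
  motif <- validate_motif(motif)
  if (nchar(seq) < nchar(motif) || nchar(seq) == 0) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                fixed = "subject")
  BiocGenerics::start(m)
}

#' Expected motif occurrences under an i.i.d. G+C background
#'
#' Closed form: the per-position match probability is the product over
#' motif positions of the background probability mass of the IUPAC class,
#' with p(G) = p(C) = gc/2 and p(A) = p(T) = (1 - gc)/2; the expectation is
#' that probability times the number of start positions per sequence times
#' the number of sequences.
#'
#' @param motif IUPAC motif string.
#' @param n_seqs Number of promoters (default 43).
#' @param seq_len Promoter length in bp (default 1500).
#' @param gc G+C fraction (default 0.35).
#' @return Expected total occurrence count (unrounded).
#' @export
expected_count <- function(motif, n_seqs = 43, seq_len = 1500, gc = 0.35) {
  motif <- validate_motif(motif)
  pb <- gc_base_probs(gc)
  classes <- iupac_classes()
  letters_m <- strsplit(motif, "")[[1]]
  p <- prod(vapply(letters_m, function(l) sum(pb[classes[[l]]]), numeric(1)))
  n_starts <- max(seq_len - length(letters_m) + 1, 0)
  n_seqs * n_starts * p
}

# Fast occurrence counting on integer-coded random sequences: simulates
# n_sets control sets of set_n sequences each as base indices 1..4
# (A,C,G,T) and counts overlapping forward-strand matches per motif,
# masking windows that would cross a sequence boundary.
simulate_null_counts <- function(motifs, n_sets, set_n, seq_len, gc,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pb <- gc_base_probs(gc)
  classes <- iupac_classes()
  base_idx <- setNames(1:4, c("A", "C", "G", "T"))
  motif_sets <- lapply(motifs, function(m) {
    lapply(strsplit(validate_motif(m), "")[[1]],
           function(l) unname(base_idx[classes[[l]]]))
  })
  total_len <- set_n * seq_len
  counts <- matrix(0L, nrow = n_sets, ncol = length(motifs))
  colnames(counts) <- motifs
  offs <- (seq_len(total_len) - 1) %% seq_len
  for (s in seq_len(n_sets)) {
    bases <- sample.int(4, total_len, replace = TRUE, prob = pb)
    for (j in seq_along(motif_sets)) {
      sets <- motif_sets[[j]]
      m <- length(sets)
      if (m > seq_len) next
      ok <- bases[1:(total_len - m + 1)] %in% sets[[1]]
      for (k in seq_len(m - 1)) {
        ok <- ok & (bases[(1 + k):(total_len - m + 1 + k)] %in% sets[[k + 1]])
      }
      valid <- offs[1:(total_len - m + 1)] <= seq_len - m
      counts[s, j] <- sum(ok & valid)
    }
  }
  counts
}

#' Monte-Carlo null distribution and empirical p-value for motif occurrences
#'
#' Simulates `n_sets` control sets, each of `set_n` i.i.d. sequences of
#' `seq_len` bp at the stated G+C content, counts total motif occurrences
#' per set, and returns the add-one empirical p-value
#' (1 + #\{sets >= observed\}) / (n_sets + 1).
#'
#' @param motif IUPAC motif string.
#' @param observed Observed total occurrence count.
#' @param n_sets Number of control sets (default 2000).
#' @param set_n Sequences per set (default 43).
#' @param seq_len Sequence length (default 1500).
#' @param gc G+C fraction (default 0.35).
#' @param seed Random seed (required for reproducibility).
#' @return List with `null_mean`, `null_sd`, `p_value` and `null_counts`
#'   (the per-set totals).
#' @export
monte_carlo_null <- function(motif, observed, n_sets = 2000, set_n = 43,
                             seq_len = 1500, gc = 0.35, seed) {
  stopifnot(n_sets >= 1)
  counts <- simulate_null_counts(motif, n_sets, set_n, seq_len, gc,
                                 seed = seed)[, 1]
  list(null_mean = mean(counts), null_sd = stats::sd(counts),
       p_value = (1 + sum(counts >= observed)) / (n_sets + 1),
       null_counts = counts)
}

#' Enrichment factor of observed over expected occurrences
#'
#' The expected count is rounded to the nearest integer (half up) before
#' division, matching how such tables are printed: the factor is infinite
#' when the expectation rounds to zero but occurrences were observed, and
#' zero when both are zero.
#'
#' @param observed Observed occurrence count.
#' @param expected Expected occurrence count (unrounded).
#' @return The enrichment factor (possibly `Inf`).
#' @export
enrichment_factor <- function(observed, expected) {
  stopifnot(observed >= 0, expected >= 0)
  er <- round_half_up(expected)
  if (er >= 1) return(observed / er)
  if (observed > 0) Inf else 0
}

#' Full enrichment analysis of motifs over a promoter set
#'
#' For each motif: occurrences and hit promoters from [scan_motif()],
#' closed-form expectation from [expected_count()] at the set's own G+C (or
#' a supplied value), enrichment factor, and Monte-Carlo p-value.
#'
#' @param promoters A `promoter_set`.
#' @param motifs Data.frame with `name`, `iupac` (see [default_motifs()]).
#' @param gc Background G+C fraction; default the promoter set's own.
#' @param n_sets Monte-Carlo control sets (default 2000).
#' @param seed Random seed.
#' @return Data.frame with one row per motif: `name`, `iupac`,
#'   `n_promoters_with_hit`, `n_occurrences`, `mean_per_hit_promoter`,
#'   `expected_occurrences`, `expected_rounded`, `enrichment_factor`,
#'   `p_value`.
#' @export
motif_enrichment <- function(promoters, motifs, gc = NULL, n_sets = 2000,
                             seed = 1) {
  gc <- gc %||% promoters$gc_content
  seqs <- promoters$sequences
  nulls <- simulate_null_counts(motifs$iupac, n_sets,
                                set_n = length(seqs),
                                seq_len = promoters$target_length,
                                gc = gc, seed = seed)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    hits <- lapply(seqs, scan_motif, motif = motifs$iupac[i])
    n_occ <- sum(lengths(hits))
    n_prom <- sum(lengths(hits) > 0)
    exp_occ <- expected_count(motifs$iupac[i], n_seqs = length(seqs),
                              seq_len = promoters$target_length, gc = gc)
    data.frame(
      name = motifs$name[i], iupac = motifs$iupac[i],
      n_promoters_with_hit = n_prom, n_occurrences = n_occ,
      mean_per_hit_promoter = if (n_prom > 0) n_occ / n_prom else 0,
      expected_occurrences = exp_occ,
      expected_rounded = round_half_up(exp_occ),
      enrichment_factor = enrichment_factor(n_occ, exp_occ),
      p_value = (1 + sum(nulls[, i] >= n_occ)) / (n_sets + 1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Positional profile of motif occurrences in fixed-width promoter bins
#'
#' Maps every match start to its upstream coordinate (-L .. -1, where -1 is
#' the base adjacent to the gene start), bins the coordinates in
#' `bin_width`-bp bins over the full target length, and computes a
#' per-bin 2.5/97.5 percentile envelope from simulated sets of the same
#' size and composition.
#'
#' @param promoters A `promoter_set`.
#' @param motif IUPAC motif string.
#' @param bin_width Bin width in bp (default 100; must divide the target
#'   length).
#' @param n_sims Number of simulated sets for the envelope (default 200).
#' @param gc Background G+C for the simulations; default the set's own.
#' @param seed Random seed.
#' @return Data.frame with one row per bin: `bin_start`, `bin_end`
#'   (upstream coordinates), `count`, `env_low`, `env_high`.
#' @export
positional_profile <- function(promoters, motif, bin_width = 100,
                               n_sims = 200, gc = NULL, seed = 1) {
  L <- promoters$target_length
  if (L %% bin_width != 0) stop("bin_width must divide target_length",
                                call. = FALSE)
  gc <- gc %||% promoters$gc_content
  nbins <- L %/% bin_width
  bin_of <- function(coord) (coord + L) %/% bin_width + 1
  count_bins <- function(seqs) {
    counts <- integer(nbins)
    for (s in seqs) {
      n <- nchar(s)
      if (n == 0) next
      for (i in scan_motif(s, motif)) {
        coord <- -(n - i + 1)
        b <- bin_of(coord)
        counts[b] <- counts[b] + 1L
      }
    }
    counts
  }
  observed <- count_bins(promoters$sequences)
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(promoters$sequences)
  sims <- matrix(0L, nrow = n_sims, ncol = nbins)
  for (r in seq_len(n_sims)) {
    sims[r, ] <- count_bins(random_dna(length(lens), L, gc))
  }
  starts <- -L + (seq_len(nbins) - 1) * bin_width
  data.frame(bin_start = starts, bin_end = starts + bin_width - 1,
             count = observed,
             env_low = apply(sims, 2, quantile, probs = 0.025),
             env_high = apply(sims, 2, quantile, probs = 0.975))
}
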