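ARCHITECTURE_CLASSES <- c("TNL", "CNL", "NL", "RNL", "XNL", "N", "CN", "XN")

#' Classify an NBS protein into one of the eight architecture classes
#'
#' Applies the standard domain-architecture scheme for plant resistance
#' proteins. The eight classes are TNL (TIR-NBS-LRR), CNL (CC-NBS-LRR), NL
#' (NBS-LRR without detectable CC), RNL (RPW8-NBS-LRR), XNL (NBS-LRR whose
#' CC evidence comes only from domain databases, not from the coiled-coil
#' predictor), N (NBS only), CN (CC-NBS) and XN (database-only CC plus NBS).
#' Coiled-coil-predictor (COILS-source) CC evidence takes precedence over
#' database evidence, so a protein with both is CNL/CN rather than XNL/XN.
#'
#' @param domains Data.frame of domain calls for a single gene, as read by
#'   [read_domain_table()].
#' @param gene_id Optional gene id; defaults to the one in `domains`.
#' @return A single architecture label.
#' @export
classify_architecture <- function(domains, gene_id = NULL) {
  if (nrow(domains) == 0) stop("no domain calls supplied", call. = FALSE)
  if (length(unique(domains$gene_id)) > 1) {
    stop("domain calls span multiple genes", call. = FALSE)
  }
  gid <- gene_id %||% domains$gene_id[1]
  has <- function(d) any(domains$domain == d)
  if (!has("NBS")) stop(gid, ": no NBS domain call; not an NBS gene",
                        call. = FALSE)
  if (has("TIR") && has("RPW8")) {
    stop(gid, ": contradictory architecture (both TIR and RPW8)",
         call. = FALSE)
  }
  cc_coils <- any(domains$domain == "CC" & domains$source == "COILS")
  cc_db <- any(domains$domain == "CC" & domains$source != "COILS")
  has_lrr <- has("LRR")
  if (has("TIR")) {
    if (!has_lrr) stop(gid, ": TIR-NBS without LRR is outside the class vocabulary",
                       call. = FALSE)
    return("TNL")
  }
  if (has("RPW8")) {
    if (!has_lrr) stop(gid, ": RPW8-NBS without LRR is outside the class vocabulary",
                       call. = FALSE)
    return("RNL")
  }
  if (has_lrr) {
    if (cc_coils) return("CNL")
    if (cc_db) return("XNL")
    return("NL")
  }
  if (cc_coils) return("CN")
  if (cc_db) return("XN")
  "N"
}

#' Tabulate architecture classes
#'
#' @param labels Character vector of architecture labels.
#' @return Named integer vector with one entry per class plus `total`.
#' @export
summarize_classes <- function(labels) {
  bad <- setdiff(unique(labels), ARCHITECTURE_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(factor(labels, levels = ARCHITECTURE_CLASSES))
  out <- as.integer(counts)
  names(out) <- ARCHITECTURE_CLASSES
  c(out, total = length(labels))
}

#' Summarize transcript-variant structure of a gene set
#'
#' @param genes Gene-model data.frame.
#' @return List with `n_models` (total transcript models), `n_loci`,
#'   `n_multi_variant_loci` and `fraction_multi`.
#' @export
variant_summary <- function(genes) {
  n_loci <- nrow(genes)
  n_multi <- sum(genes$n_variants > 1)
  list(n_models = sum(genes$n_variants),
       n_loci = n_loci,
       n_multi_variant_loci = n_multi,
       fraction_multi = if (n_loci > 0) n_multi / n_loci else 0)
}

#' Parse a degenerate amino-acid pattern
#'
#' Bracket syntax: single letters or `[...]` alternative sets, optionally
#' separated by hyphens (e.g. `"M-[KN]-D-D"`). Hyphens inside brackets are
#' ignored, so `"[GK][-QR]"` parses as the two sets `{G,K}` and `{Q,R}`.
#'
#' @param pattern Pattern string.
#' @return List of character vectors, one allowed-residue set per position.
#' @export
parse_aa_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  out <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") {
      i <- i + 1
    } else if (ch == "[") {
      j <- i + 1
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] != "-") set <- c(set, chars[j])
        j <- j + 1
      }
      if (j > length(chars)) stop("unterminated bracket in pattern", call. = FALSE)
      if (length(set) == 0) stop("empty alternative set in pattern", call. = FALSE)
      out[[length(out) + 1]] <- unique(set)
      i <- j + 1
    } else {
      out[[length(out) + 1]] <- ch
      i <- i + 1
    }
  }
  if (length(out) == 0) stop("empty pattern", call. = FALSE)
  out
}

#' Scan a protein for a degenerate consensus pattern
#'
#' Reports every 1-based start position at which each pattern position's
#' residue set admits the protein residue; overlapping matches are allowed.
#'
#' @param protein Amino-acid string.
#' @param pattern Pattern string (see [parse_aa_pattern()]) or a pre-parsed
#'   list of residue sets.
#' @return Integer vector of 1-based match start positions.
#' @export
scan_cc_consensus <- function(protein, pattern = cc_consensus_pattern()) {
  sets <- if (is.character(pattern)) parse_aa_pattern(pattern) else pattern
  if (any(vapply(sets, length, integer(1)) == 0)) {
    stop("empty alternative set in pattern", call. = FALSE)
  }
  aa <- strsplit(protein, "")[[1]]
  m <- length(sets)
  n <- length(aa)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & (aa[j:(n - m + j)] %in% sets[[j]])
  }
  which(ok)
}

#' The coiled-coil N-terminal consensus pattern
#'
#' The degenerate ~29-residue expression characteristic of the CC domain in
#' monocot CNL proteins, in bracket syntax for [scan_cc_consensus()].
#'
#' @return Pattern string.
#' @export
cc_consensus_pattern <- function() {
  paste0("M-[KN]-D-D-L-[QEK]-R-R-[KNQ]-[DR]-A-L-P-R-I-[QK]-[AH]-V-[VL]-",
         "[ENH]-[AMD]-A-E-[SR]-[GK]-[QR]-[QGI]-[EQ]-[IS]-[TE]")
}
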