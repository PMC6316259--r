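#' @importFrom stats dnorm pchisq quantile rpois setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero, matching how printed tables round .5 up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# IUPAC nucleotide classes as base sets over A/C/G/T.
iupac_classes <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(s) strsplit(s, "")[[1]])
}

# Base probabilities for an i.i.d. background at a given G+C fraction.
gc_base_probs <- function(gc) {
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Random DNA string(s) under the i.i.d. GC background.
random_dna <- function(n, len, gc) {
  p <- gc_base_probs(gc)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

check_dna_alphabet <- function(seq, allowed = c("A", "C", "G", "T", "N"),
                               what = "sequence") {
  bad <- setdiff(unique(strsplit(toupper(seq), "")[[1]]), allowed)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-%s character(s): %s", what,
                 paste(allowed, collapse = ""), paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
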