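#' Filter read-mapping hits and enforce one hit per read
#'
#' Keeps hits with alignment length strictly greater than `min_len` bp and
#' percent identity strictly greater than `min_identity`, then deduplicates
#' to a single hit per read per library, preferring highest identity, then
#' longest alignment, then lexicographically smallest gene id (so the
#' result is a function of the input multiset, not its order).
#'
#' @param hits Hit-record data.frame ([read_hit_table()]).
#' @param min_len Minimum alignment length, exclusive (default 100).
#' @param min_identity Minimum percent identity, exclusive (default 90).
#' @return Filtered, deduplicated hit data.frame.
#' @export
filter_hits <- function(hits, min_len = 100, min_identity = 90) {
  keep <- hits[hits$aln_length > min_len & hits$pct_identity > min_identity, ,
               drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  ord <- order(keep$library_id, keep$read_id, -keep$pct_identity,
               -keep$aln_length, keep$gene_id)
  keep <- keep[ord, , drop = FALSE]
  dup <- duplicated(keep[, c("library_id", "read_id")])
  out <- keep[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count filtered hits per gene and library and normalize to CPM
#'
#' @param hits Filtered hit data.frame ([filter_hits()]).
#' @param library_sizes Named integer vector, library_id -> total reads in
#'   the library (the normalization denominator).
#' @param genes Optional character vector of gene ids to include as rows
#'   even with zero hits.
#' @return An `expression_matrix`: list with `raw` (gene x library integer
#'   matrix), `normalized` (counts per million: raw x 1e6 / library size)
#'   and `library_sizes`.
#' @export
count_and_normalize <- function(hits, library_sizes, genes = NULL) {
  miss <- setdiff(unique(hits$library_id), names(library_sizes))
  if (length(miss) > 0) stop("no library size for: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be positive",
                                    call. = FALSE)
  gene_ids <- sort(unique(c(hits$gene_id, genes)))
  libs <- names(library_sizes)
  raw <- matrix(0L, nrow = length(gene_ids), ncol = length(libs),
                dimnames = list(gene_ids, libs))
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$gene_id, levels = gene_ids),
                 factor(hits$library_id, levels = libs))
    raw[] <- as.integer(tab)
  }
  normalized <- sweep(raw * 1e6, 2, library_sizes[libs], "/")
  structure(list(raw = raw, normalized = normalized,
                 library_sizes = library_sizes[libs]),
            class = "expression_matrix")
}

#' Call tissue-enriched genes by normalized count ratio
#'
#' For each gene the ratio (norm_a + pc) / (norm_b + pc) is computed with a
#' pseudo-count pc equal to the smallest positive normalized value across
#' the two libraries (1 when all counts are zero); a gene is called
#' enriched in library `lib_a` when the ratio exceeds `ratio_threshold`, in
#' `lib_b` when its reciprocal does, and `none` otherwise. MA coordinates
#' (mean normalized expression and log2 ratio) are included for plotting.
#'
#' @param mat An `expression_matrix`.
#' @param lib_a,lib_b Library ids to compare.
#' @param ratio_threshold Fold-change threshold (default 8).
#' @return Data.frame: `gene_id`, `norm_a`, `norm_b`, `mean_expr`,
#'   `log2_ratio`, `ratio`, `label` (lib_a, lib_b or "none").
#' @export
call_enrichment <- function(mat, lib_a, lib_b, ratio_threshold = 8) {
  for (l in c(lib_a, lib_b)) {
    if (!l %in% colnames(mat$normalized)) stop("library not in matrix: ", l,
                                               call. = FALSE)
  }
  a <- mat$normalized[, lib_a]
  b <- mat$normalized[, lib_b]
  pos <- c(a[a > 0], b[b > 0])
  pc <- if (length(pos)) min(pos) else 1
  ratio <- (a + pc) / (b + pc)
  label <- rep("none", length(ratio))
  label[ratio > ratio_threshold] <- lib_a
  label[1 / ratio > ratio_threshold] <- lib_b
  data.frame(gene_id = rownames(mat$normalized),
             norm_a = unname(a), norm_b = unname(b),
             mean_expr = unname((a + b) / 2),
             log2_ratio = unname(log2(ratio)),
             ratio = unname(ratio), label = label,
             stringsAsFactors = FALSE)
}
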