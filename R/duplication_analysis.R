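#' Pairwise CDS similarity by local alignment
#'
#' Aligns two coding sequences with an affine-gap local (Smith-Waterman)
#' alignment and summarizes it the way all-vs-all BLAST output is
#' summarized: percent identity over the aligned columns and percent
#' coverage of the longer sequence by the aligned region.
#'
#' @param cds_a,cds_b DNA strings (A/C/G/T/N only).
#' @param gene_a,gene_b Optional gene ids carried into the result.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters
#'   (defaults +1/-2/5/2; penalties positive).
#' @return One-row data.frame: `gene_a`, `gene_b`, `pct_identity`
#'   (matches / alignment columns x 100), `aln_length` (alignment columns),
#'   `pct_coverage` (aligned span in the longer sequence / longer length x
#'   100).
#' @export
pairwise_similarity <- function(cds_a, cds_b, gene_a = "a", gene_b = "b",
                                match = 1, mismatch = -2,
                                gap_open = 5, gap_ext = 2) {
  if (!nzchar(cds_a) || !nzchar(cds_b)) stop("empty sequence", call. = FALSE)
  check_dna_alphabet(cds_a, what = gene_a)
  check_dna_alphabet(cds_b, what = gene_b)
  # align with the longer sequence as pattern so coverage reads off directly
  swap <- nchar(cds_b) > nchar(cds_a)
  longer <- if (swap) cds_b else cds_a
  shorter <- if (swap) cds_a else cds_b
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(longer), Biostrings::DNAString(shorter),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  cols <- Biostrings::nchar(aln)
  identity <- 100 * Biostrings::nmatch(aln) / cols
  span <- IRanges::width(Biostrings::pattern(aln))
  coverage <- 100 * span / nchar(longer)
  data.frame(gene_a = gene_a, gene_b = gene_b,
             pct_identity = identity, aln_length = cols,
             pct_coverage = coverage, stringsAsFactors = FALSE)
}

#' All-vs-all pairwise similarities for a set of CDS
#'
#' @param cds Named character vector of coding sequences (names = gene ids).
#' @param ... Passed to [pairwise_similarity()].
#' @return Data.frame of all unordered pairs.
#' @export
all_vs_all_similarity <- function(cds, ...) {
  ids <- names(cds)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  if (length(ids) < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pct_identity = numeric(0), aln_length = integer(0),
                      pct_coverage = numeric(0)))
  }
  pairs <- utils::combn(ids, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pairwise_similarity(cds[[pairs[1, k]]], cds[[pairs[2, k]]],
                        gene_a = pairs[1, k], gene_b = pairs[2, k], ...)
  }))
}

#' Build multigene families by single-linkage at a similarity threshold
#'
#' Two genes are linked when their alignment identity and its coverage of
#' the longer gene both exceed the threshold (strict `>`); families are the
#' connected components of the resulting graph (single linkage), and
#' components of size one are singletons.
#'
#' @param pairs Data.frame with `gene_a`, `gene_b`, `pct_identity`,
#'   `pct_coverage`.
#' @param genes Character vector of all gene ids to partition.
#' @param threshold Percent threshold applied to both identity and coverage
#'   (one of 70, 80, 90 in the standard sweep; any value in (0, 100]
#'   accepted).
#' @return A `family_set`: list with `threshold`, `families` (list of
#'   character vectors, each of size >= 2, sorted by decreasing size) and
#'   `singletons`.
#' @export
build_families <- function(pairs, genes, threshold) {
  stopifnot(threshold > 0, threshold <= 100)
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes)
  if (length(unknown) > 0) {
    stop("edge references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- pairs$pct_identity > threshold & pairs$pct_coverage > threshold
  edges <- pairs[keep, c("gene_a", "gene_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  sizes <- lengths(groups)
  fams <- groups[sizes >= 2]
  fams <- lapply(fams, sort)
  fams <- fams[order(-lengths(fams))]
  names(fams) <- NULL
  structure(list(threshold = threshold, families = fams,
                 singletons = sort(unlist(groups[sizes == 1],
                                          use.names = FALSE)) %||% character(0)),
            class = "family_set")
}

#' Summary metrics of a family partition
#'
#' @param fs A `family_set`.
#' @param n_total Total number of genes considered (>= genes in `fs`).
#' @return List with `pct_in_families` (percent of `n_total` in families of
#'   size >= 2), `n_families`, `max_size`, `mean_size` (0 with
#'   `mean_defined = FALSE` when there are no families), and
#'   `largest_family_share` (percent of family-member genes in the largest
#'   family).
#' @export
family_metrics <- function(fs, n_total) {
  sizes <- lengths(fs$families)
  n_in <- sum(sizes)
  stopifnot(n_total >= n_in + length(fs$singletons))
  n_fam <- length(sizes)
  list(pct_in_families = 100 * n_in / n_total,
       n_families = n_fam,
       max_size = if (n_fam) max(sizes) else 0L,
       mean_size = if (n_fam) n_in / n_fam else 0,
       mean_defined = n_fam > 0,
       largest_family_share = if (n_in > 0) 100 * max(sizes) / n_in else 0)
}

# Canonicalize a gene-level homology table to best (minimum) evalue per
# unordered pair.
canonical_homology <- function(homology) {
  if (nrow(homology) == 0) return(homology)
  a <- pmin(homology$gene_a, homology$gene_b)
  b <- pmax(homology$gene_a, homology$gene_b)
  key <- paste(a, b, sep = "\r")
  ev <- tapply(homology$evalue, key, min)
  parts <- strsplit(names(ev), "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1),
             gene_b = vapply(parts, `[`, "", 2),
             evalue = as.numeric(ev), stringsAsFactors = FALSE)
}

#' Classify within-family duplicate pairs as tandem or segmental
#'
#' A within-family pair is tandem when both members lie in one detected
#' physical cluster. Otherwise the up-to-`flank` annotated genes on each
#' side of each member form two flanking blocks (fewer near chromosome
#' ends), and the pair is segmental when more than `min_pairs` cross-block
#' gene pairs are homologous at `evalue < max_evalue`; remaining pairs are
#' unclassified. A pair qualifying as both cluster-mates and
#' synteny-supported is labeled tandem.
#'
#' @param fs A `family_set`.
#' @param clusters Cluster data.frame from [detect_clusters()].
#' @param all_genes Gene-model data.frame of all annotated genes.
#' @param homology Data.frame `gene_a`, `gene_b`, `evalue` of gene-level
#'   homology hits among annotated genes (best evalue per pair is used).
#' @param flank Number of flanking genes per side (default 15).
#' @param min_pairs Homologous cross-block pairs required beyond this count
#'   for a segmental call (default 5, i.e. >= 6 pairs).
#' @param max_evalue Homology evalue cutoff (default 1e-10).
#' @return Data.frame: `gene_a`, `gene_b`, `mode` (tandem / segmental /
#'   unclassified), `n_syntenic_pairs`.
#' @export
classify_duplications <- function(fs, clusters, all_genes, homology,
                                  flank = 15, min_pairs = 5,
                                  max_evalue = 1e-10) {
  if (flank < 1) stop("flank must be >= 1", call. = FALSE)
  hom <- canonical_homology(homology)
  hom_key <- paste(hom$gene_a, hom$gene_b, sep = "\r")
  ord <- all_genes[order(all_genes$chromosome, all_genes$start), ,
                   drop = FALSE]
  pos <- split(ord$gene_id, ord$chromosome)
  flank_block <- function(gid) {
    chr <- all_genes$chromosome[all_genes$gene_id == gid]
    ids <- pos[[chr]]
    i <- match(gid, ids)
    ids[setdiff(max(1, i - flank):min(length(ids), i + flank), i)]
  }
  cluster_of <- function(gid) {
    hits <- which(vapply(clusters$members, function(m) gid %in% m, logical(1)))
    if (length(hits)) hits[1] else NA_integer_
  }
  rows <- list()
  for (fam in fs$families) {
    prs <- utils::combn(sort(fam), 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      ca <- cluster_of(a); cb <- cluster_of(b)
      if (!is.na(ca) && !is.na(cb) && ca == cb) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = a, gene_b = b, mode = "tandem",
          n_syntenic_pairs = 0L, stringsAsFactors = FALSE)
        next
      }
      blk_a <- flank_block(a)
      blk_b <- flank_block(b)
      n_syn <- 0L
      if (length(blk_a) && length(blk_b)) {
        grid <- expand.grid(x = blk_a, y = blk_b, stringsAsFactors = FALSE)
        grid <- grid[grid$x != grid$y, , drop = FALSE]
        key <- paste(pmin(grid$x, grid$y), pmax(grid$x, grid$y), sep = "\r")
        key <- unique(key)
        ev <- hom$evalue[match(key, hom_key)]
        n_syn <- sum(!is.na(ev) & ev < max_evalue)
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = a, gene_b = b,
        mode = if (n_syn > min_pairs) "segmental" else "unclassified",
        n_syntenic_pairs = n_syn, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      mode = character(0), n_syntenic_pairs = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Sweep family construction over similarity thresholds
#'
#' Builds one family partition per threshold, computes its metrics, and
#' tabulates every gene's family membership across thresholds (the data
#' behind an alluvial view of family splitting as the threshold rises).
#'
#' @param pairs Pairwise-similarity data.frame.
#' @param genes Character vector of gene ids.
#' @param thresholds Ascending percent thresholds (default `c(70, 80, 90)`).
#' @param n_total Denominator for `pct_in_families` (default
#'   `length(genes)`).
#' @return List with `family_sets` (named by threshold), `metrics`
#'   (one row per threshold) and `transitions` (gene_id plus one family-id
#'   column per threshold; singletons are `NA`).
#' @export
threshold_sweep <- function(pairs, genes, thresholds = c(70, 80, 90),
                            n_total = length(genes)) {
  stopifnot(!is.unsorted(thresholds))
  fsets <- lapply(thresholds, function(t) build_families(pairs, genes, t))
  names(fsets) <- as.character(thresholds)
  metrics <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    m <- family_metrics(fsets[[i]], n_total)
    data.frame(threshold = thresholds[i],
               pct_in_families = m$pct_in_families,
               n_families = m$n_families, max_size = m$max_size,
               mean_size = m$mean_size)
  }))
  trans <- data.frame(gene_id = sort(genes), stringsAsFactors = FALSE)
  for (i in seq_along(thresholds)) {
    fam_of <- rep(NA_integer_, nrow(trans))
    for (j in seq_along(fsets[[i]]$families)) {
      fam_of[trans$gene_id %in% fsets[[i]]$families[[j]]] <- j
    }
    trans[[paste0("family_t", thresholds[i])]] <- fam_of
  }
  list(family_sets = fsets, metrics = metrics, transitions = trans)
}
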