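#' Detect physical clusters of NBS genes on chromosomes
#'
#' A cluster is a maximal run of NBS genes on one chromosome in which every
#' consecutive pair is separated by less than `max_gap_kb` (measured
#' edge-to-edge: start of the next gene minus end of the previous) and by at
#' most `max_intervening` non-NBS annotated genes; runs shorter than
#' `min_size` are discarded. Clusters never span chromosomes.
#'
#' @param nbs_genes Gene-model data.frame of the NBS genes (subset of
#'   `all_genes` by `gene_id`).
#' @param all_genes Gene-model data.frame of all annotated genes.
#' @param max_gap_kb Maximum inter-gene distance in kb (default 200).
#' @param max_intervening Maximum number of non-NBS genes between
#'   consecutive members (default 8).
#' @param min_size Minimum number of genes per cluster (default 2).
#' @return Data.frame with one row per cluster: `cluster_id`, `chromosome`,
#'   `members` (list column of gene ids ordered by start), `n_members`,
#'   `span_kb`, `n_intervening` (total across gaps), `cluster_type`
#'   (initially `"untyped"`).
#' @export
detect_clusters <- function(nbs_genes, all_genes, max_gap_kb = 200,
                            max_intervening = 8, min_size = 2) {
  missing_ids <- setdiff(nbs_genes$gene_id, all_genes$gene_id)
  if (length(missing_ids) > 0) {
    stop("NBS gene(s) absent from the full annotation: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- list()
  cid <- 0L
  for (chr in unique(nbs_genes$chromosome)) {
    nbs <- nbs_genes[nbs_genes$chromosome == chr, , drop = FALSE]
    nbs <- nbs[order(nbs$start), , drop = FALSE]
    others <- all_genes[all_genes$chromosome == chr &
                          !(all_genes$gene_id %in% nbs_genes$gene_id), ,
                        drop = FALSE]
    n <- nrow(nbs)
    if (n == 0) next
    gap_ok <- logical(max(n - 1, 0))
    n_between <- integer(max(n - 1, 0))
    for (i in seq_len(n - 1)) {
      gap_kb <- (nbs$start[i + 1] - nbs$end[i]) / 1000
      n_between[i] <- sum(others$start > nbs$end[i] &
                            others$end < nbs$start[i + 1])
      gap_ok[i] <- gap_kb < max_gap_kb && n_between[i] <= max_intervening
    }
    # maximal runs over the pairwise-ok relation
    run_start <- 1L
    for (i in seq_len(n)) {
      boundary <- (i == n) || !gap_ok[i]
      if (boundary) {
        len <- i - run_start + 1L
        if (len >= min_size) {
          cid <- cid + 1L
          members <- nbs$gene_id[run_start:i]
          out[[cid]] <- data.frame(
            cluster_id = cid, chromosome = chr,
            n_members = len,
            span_kb = (nbs$end[i] - nbs$start[run_start]) / 1000,
            n_intervening = sum(n_between[run_start:(i - 1)]),
            cluster_type = "untyped", stringsAsFactors = FALSE)
          out[[cid]]$members <- list(members)
        }
        run_start <- i + 1L
      }
    }
  }
  if (length(out) == 0) {
    df <- data.frame(cluster_id = integer(0), chromosome = character(0),
                     n_members = integer(0), span_kb = numeric(0),
                     n_intervening = integer(0), cluster_type = character(0),
                     stringsAsFactors = FALSE)
    df$members <- list()
    return(df)
  }
  do.call(rbind, out)
}

#' Type clusters as monophyletic or mixed against a clade map
#'
#' A cluster is monophyletic when all members with a clade assignment share
#' one clade, mixed when two or more clades are present, and untyped when
#' fewer than two members carry an assignment.
#'
#' @param clusters Cluster data.frame from [detect_clusters()].
#' @param clades Named character vector `gene_id -> clade`
#'   ([read_clade_map()]).
#' @return The cluster data.frame with `cluster_type` filled in.
#' @export
type_clusters <- function(clusters, clades) {
  if (nrow(clusters) == 0) return(clusters)
  clusters$cluster_type <- vapply(clusters$members, function(m) {
    assigned <- clades[m]
    assigned <- assigned[!is.na(assigned)]
    if (length(assigned) < 2) return("untyped")
    if (length(unique(assigned)) == 1) "monophyletic" else "mixed"
  }, character(1))
  clusters
}

#' Summarize cluster membership
#'
#' @param clusters Cluster data.frame.
#' @param n_mapped Number of NBS genes placed on chromosomes.
#' @return List with `per_cluster` (cluster_id, chromosome, n_members,
#'   span_kb, members as a comma-joined string), `n_clusters`,
#'   `genes_in_clusters`, `n_singletons` (= n_mapped - genes in clusters)
#'   and `largest_cluster`.
#' @export
cluster_summary <- function(clusters, n_mapped) {
  in_clusters <- sum(clusters$n_members)
  per <- data.frame(
    cluster_id = clusters$cluster_id,
    chromosome = clusters$chromosome,
    n_members = clusters$n_members,
    span_kb = clusters$span_kb,
    n_intervening = clusters$n_intervening,
    cluster_type = clusters$cluster_type,
    members = vapply(clusters$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  list(per_cluster = per,
       n_clusters = nrow(clusters),
       genes_in_clusters = in_clusters,
       n_singletons = n_mapped - in_clusters,
       largest_cluster = if (nrow(clusters)) max(clusters$n_members) else 0L)
}

#' Chi-squared test of gene-count proportionality to chromosome length
#'
#' Tests whether genes are distributed over chromosomes at a rate
#' proportional to chromosome length: expected counts are the total count
#' apportioned by length, the statistic is the usual sum of
#' (observed - expected)^2 / expected, and the p-value comes from the
#' chi-squared upper tail with (k - 1) degrees of freedom, without
#' continuity correction. Only chromosomes present in `counts` enter the
#' test, so chromosomes known to bear zero genes should be included with a
#' zero count.
#'
#' @param counts Named integer vector, chromosome -> gene count.
#' @param lengths Named numeric vector, chromosome -> length in bp.
#' @return An `enrichment_test` list: `observed`, `expected`, `statistic`,
#'   `df`, `p_value`.
#' @export
chromosome_enrichment <- function(counts, lengths) {
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss) > 0) stop("no length for chromosome(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  lens <- lengths[names(counts)]
  if (any(lens <= 0)) stop("zero-length chromosome", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("no genes counted", call. = FALSE)
  expected <- total * lens / sum(lens)
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1
  structure(list(observed = counts, expected = expected,
                 statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE)),
            class = "enrichment_test")
}
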