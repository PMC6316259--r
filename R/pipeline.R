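#' Default pipeline configuration
#'
#' All stage thresholds at their standard values: physical clusters at
#' < 200 kb with <= 8 intervening genes and >= 2 members; family thresholds
#' 70/80/90% identity-and-coverage; synteny at 15 flanking genes per side,
#' > 5 homologous pairs at evalue < 1e-10; promoters of 1500 bp with the
#' G+C taken from the data, 2000 Monte-Carlo sets and 100-bp bins;
#' expression filters at > 100 bp, > 90% identity and a count-ratio
#' threshold of 8; coiled-coil calls at probability 0.9. Every value can be
#' overridden in the list passed to [run_pipeline()].
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    max_gap_kb = 200, max_intervening = 8, min_cluster_size = 2,
    family_thresholds = c(70, 80, 90),
    flank = 15, min_syntenic_pairs = 5, max_evalue = 1e-10,
    promoter_upstream = 1500, promoter_gc = NULL, n_sets = 2000,
    bin_width = 100,
    min_aln_length = 100, min_identity = 90, ratio_threshold = 8,
    cc_threshold = 0.9,
    promoter_exclude = character(0),
    resume = FALSE)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg
}

#' Run the full NBS gene-family analysis pipeline
#'
#' Executes the stages in dependency order — architecture classification,
#' chromosomal distribution and clustering, duplication analysis, promoter
#' cis-element enrichment, digital expression — each emitting a TSV into
#' `out_dir`, together with a `run.log` recording the package version, the
#' seed and a config checksum. With `resume = TRUE` a stage whose output
#' file already exists is skipped.
#'
#' @param config A named list or path to a YAML file. Required paths:
#'   `gff3`, `genome_fasta`, `domain_table`. Optional: `clade_map` (clusters
#'   are left untyped without it, with a warning), `homology` (gene-level
#'   homology TSV for the synteny test; duplications beyond tandem are
#'   unclassified without it), `hit_table` and `library_sizes` (named list;
#'   the expression stage is skipped without them), `motifs` (defaults to
#'   the bundled set). Threshold overrides as in
#'   [default_pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  cfg_flat <- cfg[!(names(cfg) %in% "resume")]
  cfg_sum <- sum(utf8ToInt(paste(deparse(cfg_flat), collapse = "")))
  log_line("nbsfam ", as.character(utils::packageVersion("nbsfam")),
           " seed=", cfg$seed, " config_checksum=", cfg_sum)
  set.seed(cfg$seed)
  results <- list()
  stage <- function(name, outfile, fn) {
    path <- file.path(out_dir, outfile)
    if (isTRUE(cfg$resume) && file.exists(path)) {
      log_line("stage ", name, ": resumed (output exists)")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(path), error = function(e) {
      log_line("stage ", name, ": ERROR ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("stage ", name, ": done -> ", outfile)
    res
  }

  ann <- read_annotation(cfg$gff3, cfg$genome_fasta)
  domains <- read_domain_table(cfg$domain_table)
  nbs_ids <- intersect(ann$genes$gene_id,
                       unique(domains$gene_id[domains$domain == "NBS"]))
  nbs_genes <- ann$genes[ann$genes$gene_id %in% nbs_ids, , drop = FALSE]

  results$classes <- stage("classify", "classes.tsv", function(path) {
    labels <- vapply(nbs_ids, function(g) {
      classify_architecture(domains[domains$gene_id == g, , drop = FALSE])
    }, character(1))
    tab <- summarize_classes(labels)
    write_tsv(data.frame(gene_id = nbs_ids, class = labels),
              file.path(out_dir, "gene_classes.tsv"))
    write_tsv(data.frame(class = names(tab), count = as.integer(tab)), path)
    list(labels = labels, table = tab)
  })

  results$distribution <- stage("distribution", "clusters.tsv", function(path) {
    clusters <- detect_clusters(nbs_genes, ann$genes,
                                max_gap_kb = cfg$max_gap_kb,
                                max_intervening = cfg$max_intervening,
                                min_size = cfg$min_cluster_size)
    if (!is.null(cfg$clade_map)) {
      clusters <- type_clusters(clusters, read_clade_map(cfg$clade_map))
    } else {
      warning("no clade map supplied; clusters left untyped")
      log_line("stage distribution: no clade map, clusters untyped")
    }
    summ <- cluster_summary(clusters, n_mapped = nrow(nbs_genes))
    write_tsv(summ$per_cluster, path)
    counts <- table(factor(nbs_genes$chromosome,
                           levels = names(ann$genome)))
    enr <- chromosome_enrichment(setNames(as.integer(counts), names(counts)),
                                 setNames(Biostrings::width(ann$genome),
                                          names(ann$genome)))
    write_tsv(data.frame(chromosome = names(enr$observed),
                         observed = as.integer(enr$observed),
                         expected = as.numeric(enr$expected)),
              file.path(out_dir, "chromosome_counts.tsv"))
    log_line(sprintf("chi-squared=%.4f df=%d p=%.3g", enr$statistic,
                     enr$df, enr$p_value))
    list(clusters = clusters, summary = summ, enrichment = enr)
  })

  results$duplication <- stage("duplication", "families.tsv", function(path) {
    cds <- setNames(nbs_genes$cds, nbs_genes$gene_id)
    pairs <- all_vs_all_similarity(cds)
    sweep <- threshold_sweep(pairs, names(cds),
                             thresholds = cfg$family_thresholds)
    write_tsv(sweep$transitions, path)
    write_tsv(sweep$metrics, file.path(out_dir, "family_metrics.tsv"))
    homology <- if (!is.null(cfg$homology)) {
      read.delim(cfg$homology, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_a = character(0), gene_b = character(0),
                 evalue = numeric(0))
    }
    fs <- sweep$family_sets[[1]]
    clusters <- results$distribution$clusters %||%
      detect_clusters(nbs_genes, ann$genes, max_gap_kb = cfg$max_gap_kb,
                      max_intervening = cfg$max_intervening,
                      min_size = cfg$min_cluster_size)
    dups <- classify_duplications(
      fs, clusters, ann$genes, homology,
      flank = cfg$flank, min_pairs = cfg$min_syntenic_pairs,
      max_evalue = cfg$max_evalue)
    write_tsv(dups, file.path(out_dir, "duplications.tsv"))
    list(pairs = pairs, sweep = sweep, duplications = dups)
  })

  results$promoters <- stage("promoters", "promoter_enrichment.tsv",
                             function(path) {
    proms <- extract_promoters(ann$genome, nbs_genes,
                               upstream = cfg$promoter_upstream,
                               exclude = cfg$promoter_exclude)
    motifs <- if (!is.null(cfg$motifs)) {
      read.delim(cfg$motifs, stringsAsFactors = FALSE)
    } else {
      default_motifs()
    }
    enr <- motif_enrichment(proms, motifs, gc = cfg$promoter_gc,
                            n_sets = cfg$n_sets, seed = cfg$seed)
    write_tsv(enr, path)
    list(promoters = proms, enrichment = enr)
  })

  if (!is.null(cfg$hit_table) && !is.null(cfg$library_sizes)) {
    results$expression <- stage("expression", "expression.tsv",
                                function(path) {
      hits <- filter_hits(read_hit_table(cfg$hit_table),
                          min_len = cfg$min_aln_length,
                          min_identity = cfg$min_identity)
      sizes <- unlist(cfg$library_sizes)
      mat <- count_and_normalize(hits, sizes, genes = nbs_ids)
      libs <- names(sizes)
      calls <- call_enrichment(mat, libs[1], libs[2],
                               ratio_threshold = cfg$ratio_threshold)
      write_tsv(calls, path)
      list(matrix = mat, calls = calls)
    })
  } else {
    log_line("stage expression: skipped (no hit table / library sizes)")
  }
  log_line("pipeline complete")
  invisible(results)
}
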