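#' Read a genome FASTA into a named DNAStringSet
#'
#' Sequences are upper-cased on read; IUPAC ambiguity codes are preserved.
#' Chromosome names are taken as the first whitespace-delimited token of each
#' FASTA header and must be unique.
#'
#' @param fasta_path Path to a (possibly multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome_fasta <- function(fasta_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- nm
  x
}

# Light structural validation so malformed GFF3 is reported with a line number.
validate_gff3_lines <- function(gff3_path) {
  lines <- readLines(gff3_path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9) {
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-delimited fields, found %d",
                   i, nf), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 annotation and genome FASTA
#'
#' Builds one gene model per locus (one row per `gene` feature). The number
#' of transcript variants is the count of `mRNA` children of each gene;
#' transcripts without a parent gene are ignored with a warning. The CDS of
#' each locus is spliced from the CDS features of its first transcript (by
#' ID order) when present, otherwise taken as the full gene span; minus-strand
#' CDS are reverse-complemented. Proteins are translated when the CDS length
#' is divisible by three.
#'
#' @param gff3_path Path to a GFF3 annotation. GFF3 is the only supported
#'   annotation dialect.
#' @param fasta_path Path to the genome FASTA.
#' @return A list with components `genes` (a data.frame with columns
#'   `gene_id`, `chromosome`, `start`, `end`, `strand`, `n_variants`, `cds`,
#'   `protein`; coordinates 1-based inclusive) and `genome`
#'   (a named [Biostrings::DNAStringSet]).
#' @export
read_annotation <- function(gff3_path, fasta_path) {
  genome <- read_genome_fasta(fasta_path)
  validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0) stop("no gene features in ", gff3_path, call. = FALSE)
  gene_ids <- as.character(genes$ID)

  mrna <- gr[type == "mRNA"]
  mrna_parent <- vapply(as.list(mrna$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  orphan <- !is.na(mrna_parent) & !(mrna_parent %in% gene_ids)
  if (any(orphan) || anyNA(mrna_parent)) {
    warning(sum(orphan | is.na(mrna_parent)),
            " transcript(s) without a parent gene ignored")
  }

  cds <- gr[type == "CDS"]
  cds_parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  chr <- as.character(GenomicRanges::seqnames(genes))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr) > 0) {
    stop("gene(s) reference chromosome(s) absent from the genome FASTA: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }

  n_var <- integer(length(genes))
  cds_seq <- character(length(genes))
  prot_seq <- rep(NA_character_, length(genes))
  starts <- GenomicRanges::start(genes)
  ends <- GenomicRanges::end(genes)
  strands <- as.character(GenomicRanges::strand(genes))
  strands[!strands %in% c("+", "-")] <- "+"

  mrna_ids <- as.character(mrna$ID)
  for (i in seq_along(genes)) {
    gid <- gene_ids[i]
    kids <- which(mrna_parent == gid)
    n_var[i] <- max(length(kids), 1L)
    # representative transcript = first mRNA child by ID
    rep_tx <- if (length(kids)) mrna_ids[kids][order(mrna_ids[kids])][1] else NA
    cparts <- if (!is.na(rep_tx)) which(cds_parent == rep_tx) else integer(0)
    if (length(cparts) > 0) {
      cp <- cds[cparts]
      cp <- cp[order(GenomicRanges::start(cp))]
      pieces <- vapply(seq_along(cp), function(k) {
        as.character(Biostrings::subseq(genome[[chr[i]]],
                                        GenomicRanges::start(cp)[k],
                                        GenomicRanges::end(cp)[k]))
      }, character(1))
      s <- paste(pieces, collapse = "")
    } else {
      s <- as.character(Biostrings::subseq(genome[[chr[i]]], starts[i], ends[i]))
    }
    if (strands[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    cds_seq[i] <- s
    if (nchar(s) %% 3 == 0) {
      prot_seq[i] <- tryCatch(
        suppressWarnings(as.character(
          Biostrings::translate(Biostrings::DNAString(s),
                                if.fuzzy.codon = "X"))),
        error = function(e) NA_character_)
    }
  }

  gene_df <- data.frame(
    gene_id = gene_ids, chromosome = chr, start = starts, end = ends,
    strand = strands, n_variants = n_var, cds = cds_seq, protein = prot_seq,
    stringsAsFactors = FALSE)
  validate_gene_models(gene_df)
  list(genes = gene_df, genome = genome)
}

validate_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  req <- c("gene_id", "chromosome", "start", "end", "strand", "n_variants")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(genes$start > genes$end)) stop("gene with start > end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'",
                                                call. = FALSE)
  if (any(genes$n_variants < 1)) stop("n_variants must be >= 1", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  invisible(genes)
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` feature per row and `n_variants` `mRNA` children per
#' gene, so that [read_annotation()] round-trips coordinates, strands and
#' variant counts exactly.
#'
#' @param genes Gene-model data.frame as returned by [read_annotation()].
#' @param gff3_path Output path.
#' @export
write_annotation <- function(genes, gff3_path) {
  validate_gene_models(genes)
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tnbsfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chromosome, g$start, g$end, g$strand, g$gene_id), con)
    for (k in seq_len(g$n_variants)) {
      writeLines(sprintf("%s\tnbsfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t%d;Parent=%s",
                         g$chromosome, g$start, g$end, g$strand,
                         g$gene_id, k, g$gene_id), con)
    }
  }
  invisible(gff3_path)
}

DOMAIN_VOCAB <- c("TIR", "CC", "NBS", "LRR", "RPW8")
SOURCE_VOCAB <- c("COILS", "CDD", "PFAM", "SMART", "OTHER")

#' Read a per-protein domain-call table
#'
#' Expects a tab-delimited file with header columns `gene_id`, `domain`,
#' `start`, `end`, `source`, `score`. Domains are validated against the
#' closed vocabulary TIR/CC/NBS/LRR/RPW8 and sources against
#' COILS/CDD/PFAM/SMART/OTHER; amino-acid coordinates are 1-based inclusive.
#'
#' @param tsv_path Path to the TSV.
#' @return A data.frame of domain calls, row order preserved.
#' @export
read_domain_table <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("gene_id", "domain", "start", "end", "source", "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("domain table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(df[, req])
  bad_d <- setdiff(unique(df$domain), DOMAIN_VOCAB)
  if (length(bad_d)) stop("unknown domain token(s): ",
                          paste(bad_d, collapse = ", "), call. = FALSE)
  bad_s <- setdiff(unique(df$source), SOURCE_VOCAB)
  if (length(bad_s)) stop("unknown source token(s): ",
                          paste(bad_s, collapse = ", "), call. = FALSE)
  if (any(df$start > df$end)) stop("domain call with start > end", call. = FALSE)
  df[, req]
}

#' Read a gene-to-clade assignment
#'
#' Accepts either a two-column TSV (`gene_id`, `clade`) or a newick tree
#' whose leaves are gene ids. For a tree, each leaf is assigned the label of
#' its nearest labeled ancestor (internal node labels, optionally translated
#' through `node_labels`); leaves with no labeled ancestor are left
#' unassigned.
#'
#' @param path Path to the TSV or newick file.
#' @param node_labels Optional named character vector mapping internal-node
#'   labels in the tree to clade labels; defaults to using node labels as-is.
#' @return A named character vector `gene_id -> clade`.
#' @export
read_clade_map <- function(path, node_labels = NULL) {
  first <- trimws(readLines(path, n = 1, warn = FALSE))
  if (startsWith(first, "(")) {
    tree <- ape::read.tree(path)
    if (anyDuplicated(tree$tip.label)) {
      stop("duplicate leaf name(s) in tree: ",
           paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                 collapse = ", "), call. = FALSE)
    }
    ntip <- length(tree$tip.label)
    labs <- tree$node.label %||% rep("", tree$Nnode)
    parent_of <- integer(ntip + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    out <- character(0)
    for (i in seq_len(ntip)) {
      node <- i
      clade <- NA_character_
      while (parent_of[node] != 0) {
        node <- parent_of[node]
        lab <- labs[node - ntip]
        if (nzchar(lab)) {
          clade <- if (!is.null(node_labels)) unname(node_labels[lab]) else lab
          break
        }
      }
      if (!is.na(clade)) out[tree$tip.label[i]] <- clade
    }
    return(out)
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene_id", "clade"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in clade map",
                                      call. = FALSE)
  if (any(!nzchar(df$clade))) stop("empty clade label", call. = FALSE)
  setNames(df$clade, df$gene_id)
}

#' Read a read-mapping hit table
#'
#' Tab-delimited with header `read_id`, `gene_id`, `aln_length`,
#' `pct_identity`, `library_id` — the shape of tabular mapper output.
#'
#' @param tsv_path Path to the TSV.
#' @return A data.frame of hit records.
#' @export
read_hit_table <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("read_id", "gene_id", "aln_length", "pct_identity", "library_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("hit table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    if (any(df$aln_length < 1)) stop("aln_length must be >= 1", call. = FALSE)
    if (any(df$pct_identity < 0 | df$pct_identity > 100)) {
      stop("pct_identity must be in [0, 100]", call. = FALSE)
    }
  }
  df[, req]
}

#' Read an externally computed pairwise-hit table
#'
#' Six tab-delimited columns with header: `gene_a`, `gene_b`,
#' `pct_identity`, `aln_length`, `pct_coverage`, `evalue` — so all-vs-all
#' BLAST output summarized per gene pair can be used unchanged in place of
#' the built-in aligner.
#'
#' @param tsv_path Path to the TSV.
#' @return A data.frame of pairwise similarities.
#' @export
read_pairwise_hits <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("gene_a", "gene_b", "pct_identity", "aln_length", "pct_coverage",
           "evalue")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pairwise hit table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df[, req]
}

# Shared writer: tab-delimited with header, no quoting.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
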