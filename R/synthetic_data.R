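#' Build a simulation recipe
#'
#' Defines the planted structure of a synthetic genome study: chromosomes
#' with gene clusters obeying (or violating) the physical-cluster rule,
#' multigene families generated by copy-and-mutate at controlled
#' divergence, one segmentally duplicated block with controlled
#' flanking-gene homology, promoters at a stated G+C with motifs planted at
#' controlled rates and positions, and expression hit tables with
#' controlled per-library means. Defaults mirror the study conditions of
#' the real analysis: 1500-bp promoters at 35% G+C in sets of 43, clusters
#' under the <200 kb / <=8 intervening rule, family divergence tiers at 5%
#' and 25% substitution, and a segmental block sharing 8 flanking homologs.
#'
#' @param seed Mandatory integer seed; every generator is a pure function
#'   of (recipe, seed).
#' @param n_chromosomes,chrom_length Genome geometry (default 2 x 3 Mb).
#' @param planted_clusters List of cluster specs: `chromosome` (index),
#'   `n_genes`, `gap_kb` (edge-to-edge gap between consecutive members),
#'   `n_intervening` (non-NBS genes inside each gap).
#' @param n_singletons Additional isolated NBS genes on chromosome 1.
#' @param family_tiers List of tiers: `n_genes`, `rate` (per-site
#'   substitution divergence from the tier ancestor). Tiers claim NBS gene
#'   slots in order: cluster slots first, then singletons.
#' @param segmental_blocks List of block specs: `n_flank_homologs`,
#'   `block_size` (flanking genes per side copied to the next chromosome
#'   together with a mutated copy of the last tier-1 singleton).
#' @param genome_gc,promoter_gc Background G+C fractions (default 0.35).
#' @param cds_len,filler_len NBS and filler CDS lengths in bp.
#' @param n_promoters,promoter_length Promoter-set geometry (default 43 x
#'   1500 bp).
#' @param planted_motifs List of motif plantings: `name`, `iupac`, `rate`
#'   (expected injections per promoter), `position` (fixed upstream
#'   coordinate, e.g. -550, or NULL for uniform).
#' @param expression_truth Data.frame `gene_id`, `mean_a`, `mean_b` of true
#'   per-library mean read counts, or NULL.
#' @param fail_frac Fraction of simulated reads drawn below the length /
#'   identity filters (default 0.3).
#' @return A `simulation_recipe` list.
#' @export
simulation_recipe <- function(seed,
                              n_chromosomes = 2,
                              chrom_length = 3e6,
                              planted_clusters = list(
                                list(chromosome = 1, n_genes = 3,
                                     gap_kb = 50, n_intervening = 2),
                                list(chromosome = 1, n_genes = 2,
                                     gap_kb = 30, n_intervening = 0)),
                              n_singletons = 3,
                              family_tiers = list(
                                list(n_genes = 4, rate = 0.05),
                                list(n_genes = 2, rate = 0.25)),
                              segmental_blocks = list(
                                list(n_flank_homologs = 8, block_size = 15)),
                              genome_gc = 0.35,
                              promoter_gc = 0.35,
                              cds_len = 480,
                              filler_len = 300,
                              n_promoters = 43,
                              promoter_length = 1500,
                              planted_motifs = list(),
                              expression_truth = NULL,
                              fail_frac = 0.3) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rates <- vapply(family_tiers, `[[`, numeric(1), "rate")
  if (any(rates < 0 | rates > 1)) stop("tier rates must be in [0, 1]",
                                       call. = FALSE)
  if (promoter_gc <= 0 || promoter_gc >= 1) stop("promoter_gc in (0,1)",
                                                 call. = FALSE)
  n_cluster_slots <- sum(vapply(planted_clusters, `[[`, numeric(1), "n_genes"))
  n_tier_slots <- sum(vapply(family_tiers, `[[`, numeric(1), "n_genes"))
  if (n_tier_slots > n_cluster_slots + n_singletons) {
    stop("family tiers claim more NBS slots than exist", call. = FALSE)
  }
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length,
                 planted_clusters = planted_clusters,
                 n_singletons = n_singletons,
                 family_tiers = family_tiers,
                 segmental_blocks = segmental_blocks,
                 genome_gc = genome_gc, promoter_gc = promoter_gc,
                 cds_len = cds_len, filler_len = filler_len,
                 n_promoters = n_promoters,
                 promoter_length = promoter_length,
                 planted_motifs = planted_motifs,
                 expression_truth = expression_truth,
                 fail_frac = fail_frac),
            class = "simulation_recipe")
}

# Substitute exactly round(rate * len) distinct positions to a different
# base, so pairwise identity to the template is analytic: (1 - rate) * 100.
mutate_seq <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  n_mut <- round(rate * length(v))
  if (n_mut == 0) return(seq)
  pos <- sample(length(v), n_mut)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

#' Simulate a genome with planted clusters, families and a segmental block
#'
#' Lays out filler and NBS genes along i.i.d.-background chromosomes.
#' Cluster members are placed at their specified edge-to-edge gaps with the
#' specified number of filler genes inside each gap; separate gene islands
#' are spaced > 200 kb apart so planted clusters are exactly the detectable
#' ones. Family tiers claim NBS slots in order (cluster slots first, then
#' singletons): the first member of a tier carries the tier ancestor CDS
#' and the rest carry copies mutated at the tier rate. Each segmental block
#' copies the last tier-1 singleton plus its flanking fillers to the next
#' chromosome; the stated number of flank pairs keep recognizable homology,
#' which is recorded in the emitted homology table.
#'
#' @param recipe A `simulation_recipe`.
#' @param out_dir Optional directory; when given, writes `genome.fasta`,
#'   `genes.gff3`, `cds.fasta`, `domains.tsv`, `clade_map.tsv`,
#'   `homology.tsv` and the truth tables as TSV.
#' @return List with `genome` (DNAStringSet), `genes` (all gene models),
#'   `nbs_ids`, `homology`, and `truth` (list of `clusters`, `families`,
#'   `duplications`, `architecture` data.frames).
#' @export
simulate_genome <- function(recipe, out_dir = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed)
  r <- recipe
  island_gap <- 250000          # > 200 kb so islands never merge
  intra_gap <- 5000             # filler-to-filler spacing within an island
  flank_run <- 16               # fillers on each side of every NBS island

  filler_count <- 0
  new_filler <- function(cds = NULL) {
    filler_count <<- filler_count + 1
    list(gene_id = sprintf("FIL%03d", filler_count), type = "filler",
         cds = cds %||% random_dna(1, r$filler_len, r$genome_gc))
  }

  # --- NBS slot bookkeeping -------------------------------------------------
  n_cluster_slots <- sum(vapply(r$planted_clusters, `[[`, numeric(1), "n_genes"))
  n_slots <- n_cluster_slots + r$n_singletons
  slot_cds <- vector("character", n_slots)
  slot_family <- rep(NA_integer_, n_slots)
  slot_rate <- rep(NA_real_, n_slots)
  slot <- 1
  for (ti in seq_along(r$family_tiers)) {
    tier <- r$family_tiers[[ti]]
    anc <- random_dna(1, r$cds_len, r$genome_gc)
    for (k in seq_len(tier$n_genes)) {
      slot_cds[slot] <- if (k == 1) anc else mutate_seq(anc, tier$rate)
      slot_family[slot] <- ti
      slot_rate[slot] <- tier$rate
      slot <- slot + 1
    }
  }
  while (slot <= n_slots) {
    slot_cds[slot] <- random_dna(1, r$cds_len, r$genome_gc)
    slot <- slot + 1
  }
  nbs_ids <- sprintf("NBS%02d", seq_len(n_slots))

  # --- island layout per chromosome ----------------------------------------
  # each island: flank_run fillers, the NBS genes (with in-gap fillers), and
  # flank_run fillers again
  chrom_items <- vector("list", r$n_chromosomes)  # list of (gene list)
  for (i in seq_len(r$n_chromosomes)) chrom_items[[i]] <- list()
  add_island <- function(chr, nbs_slots, gap_kb = NULL, n_intervening = 0) {
    items <- list()
    for (k in seq_len(flank_run)) items <- c(items, list(c(new_filler(),
                                                           gap = intra_gap)))
    for (j in seq_along(nbs_slots)) {
      s <- nbs_slots[j]
      if (j == 1) {
        items <- c(items, list(c(list(gene_id = nbs_ids[s], type = "nbs",
                                      cds = slot_cds[s]), gap = intra_gap)))
      } else {
        gap_bp <- gap_kb * 1000
        if (n_intervening > 0) {
          # spread the intervening fillers evenly inside the gap
          seg <- (gap_bp - n_intervening * r$filler_len) %/% (n_intervening + 1)
          for (k in seq_len(n_intervening)) {
            items <- c(items, list(c(new_filler(), gap = seg)))
          }
          last_gap <- gap_bp - n_intervening * r$filler_len -
            n_intervening * seg
          items <- c(items, list(c(list(gene_id = nbs_ids[s], type = "nbs",
                                        cds = slot_cds[s]), gap = last_gap)))
        } else {
          items <- c(items, list(c(list(gene_id = nbs_ids[s], type = "nbs",
                                        cds = slot_cds[s]), gap = gap_bp)))
        }
      }
    }
    for (k in seq_len(flank_run)) items <- c(items, list(c(new_filler(),
                                                           gap = intra_gap)))
    items[[1]]$gap <- island_gap
    chrom_items[[chr]] <<- c(chrom_items[[chr]], items)
    invisible(NULL)
  }

  truth_clusters <- list()
  slot_ptr <- 1
  for (ci in seq_along(r$planted_clusters)) {
    cl <- r$planted_clusters[[ci]]
    slots <- slot_ptr:(slot_ptr + cl$n_genes - 1)
    add_island(cl$chromosome, slots, gap_kb = cl$gap_kb,
               n_intervening = cl$n_intervening)
    detectable <- cl$gap_kb < 200 && cl$n_intervening <= 8 && cl$n_genes >= 2
    truth_clusters[[ci]] <- data.frame(
      gene_id = nbs_ids[slots], cluster = if (detectable) ci else NA_integer_,
      stringsAsFactors = FALSE)
    slot_ptr <- slot_ptr + cl$n_genes
  }
  singleton_slots <- if (r$n_singletons > 0) slot_ptr:(slot_ptr + r$n_singletons - 1) else integer(0)
  for (s in singleton_slots) add_island(1, s)

  # --- segmental blocks -----------------------------------------------------
  homology <- list()
  seg_truth <- list()
  seg_count <- 0
  for (bi in seq_along(r$segmental_blocks)) {
    blk <- r$segmental_blocks[[bi]]
    # source: last tier-1 singleton (falls back to last tier-1 slot)
    tier1_slots <- which(slot_family == 1)
    src_single <- intersect(tier1_slots, singleton_slots)
    src <- if (length(src_single)) src_single[length(src_single)] else
      tier1_slots[length(tier1_slots)]
    target_chr <- min(r$n_chromosomes, 1 + bi)
    seg_count <- seg_count + 1
    copy_id <- sprintf("NBSSEG%02d", seg_count)
    copy_cds <- mutate_seq(slot_cds[src], 0.02)
    # flanking block around the copy: block_size fillers per side, the
    # n_flank_homologs nearest ones homologous to the source island fillers
    src_chr_items <- chrom_items[[1]]
    src_idx <- which(vapply(src_chr_items, function(x)
      identical(x$gene_id, nbs_ids[src]), logical(1)))
    side <- blk$n_flank_homologs %/% 2
    extra <- blk$n_flank_homologs - 2 * side
    left_src <- vapply(src_chr_items[(src_idx - side - extra):(src_idx - 1)],
                       `[[`, "", "gene_id")
    right_src <- vapply(src_chr_items[(src_idx + 1):(src_idx + side)],
                        `[[`, "", "gene_id")
    hom_src <- c(left_src[seq_len(side + extra)], right_src)
    src_cds_of <- function(id) {
      for (x in src_chr_items) if (identical(x$gene_id, id)) return(x$cds)
      stop("internal: source gene not found")
    }
    items <- list()
    n_left <- blk$block_size
    n_right <- blk$block_size
    left_hom <- hom_src[seq_len(side + extra)]
    right_hom <- hom_src[(side + extra + 1):length(hom_src)]
    for (k in seq_len(n_left)) {
      # homologous fillers sit immediately left of the copy
      j <- n_left - k + 1
      if (j <= length(left_hom)) {
        f <- new_filler(cds = mutate_seq(src_cds_of(left_hom[j]), 0.02))
        homology[[length(homology) + 1]] <- data.frame(
          gene_a = left_hom[j], gene_b = f$gene_id, evalue = 1e-50,
          stringsAsFactors = FALSE)
      } else {
        f <- new_filler()
      }
      items <- c(items, list(c(f, gap = intra_gap)))
    }
    items <- c(items, list(c(list(gene_id = copy_id, type = "nbs",
                                  cds = copy_cds), gap = intra_gap)))
    for (k in seq_len(n_right)) {
      if (k <= length(right_hom)) {
        f <- new_filler(cds = mutate_seq(src_cds_of(right_hom[k]), 0.02))
        homology[[length(homology) + 1]] <- data.frame(
          gene_a = right_hom[k], gene_b = f$gene_id, evalue = 1e-50,
          stringsAsFactors = FALSE)
      } else {
        f <- new_filler()
      }
      items <- c(items, list(c(f, gap = intra_gap)))
    }
    items[[1]]$gap <- island_gap
    chrom_items[[target_chr]] <- c(chrom_items[[target_chr]], items)
    seg_truth[[bi]] <- data.frame(gene_a = nbs_ids[src], gene_b = copy_id,
                                  mode = "segmental", stringsAsFactors = FALSE)
    slot_cds <- c(slot_cds, copy_cds)
    slot_family <- c(slot_family, slot_family[src])
    slot_rate <- c(slot_rate, 0.02)
    nbs_ids <- c(nbs_ids, copy_id)
  }

  # --- coordinates and sequences -------------------------------------------
  gene_rows <- list()
  chrom_names <- sprintf("chr%d", seq_len(r$n_chromosomes))
  chrom_seqs <- character(r$n_chromosomes)
  for (i in seq_len(r$n_chromosomes)) {
    cursor <- 10000
    for (it in chrom_items[[i]]) {
      start <- cursor + it$gap
      end <- start + nchar(it$cds) - 1
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = it$gene_id, chromosome = chrom_names[i],
        start = start, end = end, strand = "+", n_variants = 1L,
        cds = it$cds, protein = NA_character_, type = it$type,
        stringsAsFactors = FALSE)
      cursor <- end
    }
    if (cursor + 10000 > r$chrom_length) {
      stop("geometry overflow: planted genes exceed chromosome length ",
           r$chrom_length, call. = FALSE)
    }
    bg <- random_dna(1, r$chrom_length, r$genome_gc)
    chrom_seqs[i] <- bg
  }
  genes <- do.call(rbind, gene_rows)
  # embed CDS into the background at its coordinates
  for (i in seq_len(r$n_chromosomes)) {
    s <- chrom_seqs[i]
    rows <- genes[genes$chromosome == chrom_names[i], , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      substr(s, rows$start[k], rows$end[k]) <- rows$cds[k]
    }
    chrom_seqs[i] <- s
  }
  genome <- Biostrings::DNAStringSet(chrom_seqs)
  names(genome) <- chrom_names

  # --- truth tables ---------------------------------------------------------
  truth_clusters <- do.call(rbind, truth_clusters)
  fam_rows <- data.frame(gene_id = nbs_ids,
                         family = slot_family,
                         rate = slot_rate, stringsAsFactors = FALSE)
  dup_rows <- list()
  for (ci in seq_along(r$planted_clusters)) {
    members <- truth_clusters$gene_id[which(truth_clusters$cluster == ci)]
    if (length(members) >= 2) {
      fam_of <- fam_rows$family[match(members, fam_rows$gene_id)]
      prs <- utils::combn(members, 2)
      for (k in seq_len(ncol(prs))) {
        fa <- fam_of[match(prs[1, k], members)]
        fb <- fam_of[match(prs[2, k], members)]
        if (!is.na(fa) && !is.na(fb) && fa == fb) {
          dup_rows[[length(dup_rows) + 1]] <- data.frame(
            gene_a = prs[1, k], gene_b = prs[2, k], mode = "tandem",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  dup_truth <- rbind(do.call(rbind, dup_rows) %||%
                       data.frame(gene_a = character(0), gene_b = character(0),
                                  mode = character(0)),
                     do.call(rbind, seg_truth))
  # remaining within-family pairs are unclassified by construction
  for (fi in unique(stats::na.omit(fam_rows$family))) {
    mem <- sort(fam_rows$gene_id[which(fam_rows$family == fi)])
    if (length(mem) < 2) next
    prs <- utils::combn(mem, 2)
    for (k in seq_len(ncol(prs))) {
      a <- pmin(prs[1, k], prs[2, k]); b <- pmax(prs[1, k], prs[2, k])
      known <- any(pmin(dup_truth$gene_a, dup_truth$gene_b) == a &
                     pmax(dup_truth$gene_a, dup_truth$gene_b) == b)
      if (!known) {
        dup_truth <- rbind(dup_truth, data.frame(
          gene_a = a, gene_b = b, mode = "unclassified",
          stringsAsFactors = FALSE))
      }
    }
  }

  # synthetic domain calls + clades so classification and typing can run
  arch_cycle <- c("CNL", "NL", "RNL", "N", "CN")
  arch <- arch_cycle[(seq_along(nbs_ids) - 1) %% length(arch_cycle) + 1]
  dom_rows <- list()
  for (k in seq_along(nbs_ids)) {
    gid <- nbs_ids[k]
    calls <- switch(arch[k],
      CNL = list(c("CC", "COILS"), c("NBS", "CDD"), c("LRR", "PFAM")),
      NL = list(c("NBS", "CDD"), c("LRR", "PFAM")),
      RNL = list(c("RPW8", "PFAM"), c("NBS", "CDD"), c("LRR", "PFAM")),
      N = list(c("NBS", "CDD")),
      CN = list(c("CC", "COILS"), c("NBS", "CDD")))
    for (cl in calls) {
      dom_rows[[length(dom_rows) + 1]] <- data.frame(
        gene_id = gid, domain = cl[1], start = 1, end = 50, source = cl[2],
        score = 1.0, stringsAsFactors = FALSE)
    }
  }
  domains <- do.call(rbind, dom_rows)
  clade_cycle <- c("Ia", "Ib", "II", "III")
  clades <- setNames(
    ifelse(!is.na(fam_rows$family), "Ia",
           clade_cycle[(seq_along(nbs_ids) - 1) %% 4 + 1]),
    nbs_ids)

  homology <- do.call(rbind, homology) %||%
    data.frame(gene_a = character(0), gene_b = character(0),
               evalue = numeric(0))
  out <- list(genome = genome, genes = genes, nbs_ids = nbs_ids,
              domains = domains, clades = clades, homology = homology,
              truth = list(clusters = truth_clusters, families = fam_rows,
                           duplications = dup_truth,
                           architecture = data.frame(gene_id = nbs_ids,
                                                     class = arch,
                                                     stringsAsFactors = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(fa, file.path(out_dir, "genome.fasta"))
    write_annotation(out$genes[, !(names(out$genes) %in% "type")],
                     file.path(out_dir, "genes.gff3"))
    cds <- Biostrings::DNAStringSet(setNames(genes$cds, genes$gene_id))
    Biostrings::writeXStringSet(cds, file.path(out_dir, "cds.fasta"))
    write_tsv(domains, file.path(out_dir, "domains.tsv"))
    write.table(data.frame(gene_id = names(clades), clade = clades),
                file.path(out_dir, "clade_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_tsv(homology, file.path(out_dir, "homology.tsv"))
    write_tsv(out$truth$clusters, file.path(out_dir, "truth_clusters.tsv"))
    write_tsv(out$truth$families, file.path(out_dir, "truth_families.tsv"))
    write_tsv(out$truth$duplications,
              file.path(out_dir, "truth_duplications.tsv"))
  }
  out
}

#' Simulate a promoter set with planted motif occurrences
#'
#' Background sequences are i.i.d. at the recipe's promoter G+C; each
#' planted motif is injected `floor(rate)` times per promoter plus one more
#' with probability `rate - floor(rate)`, either at a fixed upstream
#' coordinate or uniformly, overwriting the background with a concrete
#' realization of the IUPAC pattern. Collisions with previously planted
#' occurrences are re-drawn up to 100 times, then raise an error.
#'
#' @param recipe A `simulation_recipe` (fields `n_promoters`,
#'   `promoter_length`, `promoter_gc`, `planted_motifs`, `seed`).
#' @param seed Optional seed override.
#' @return List with `promoters` (a `promoter_set`) and `truth`
#'   (data.frame `promoter`, `motif`, `position` (1-based), `coord`
#'   (upstream coordinate)).
#' @export
simulate_promoters <- function(recipe, seed = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(seed %||% recipe$seed)
  n <- recipe$n_promoters
  L <- recipe$promoter_length
  classes <- iupac_classes()
  seqs <- random_dna(n, L, recipe$promoter_gc)
  names(seqs) <- sprintf("P%03d", seq_len(n))
  truth <- list()
  occupied <- replicate(n, integer(0), simplify = FALSE)
  for (pm in recipe$planted_motifs) {
    iupac <- validate_motif(pm$iupac)
    m <- nchar(iupac)
    sets <- lapply(strsplit(iupac, "")[[1]], function(l) classes[[l]])
    for (i in seq_len(n)) {
      k <- floor(pm$rate) + (stats::runif(1) < pm$rate - floor(pm$rate))
      for (j in seq_len(k)) {
        placed <- FALSE
        for (try in seq_len(100)) {
          pos <- if (!is.null(pm$position)) {
            L + pm$position + 1          # upstream coordinate -> 1-based index
          } else {
            sample(L - m + 1, 1)
          }
          span <- pos:(pos + m - 1)
          if (length(intersect(span, occupied[[i]])) == 0) {
            realization <- vapply(sets, function(s) sample(s, 1), character(1))
            substr(seqs[i], pos, pos + m - 1) <- paste(realization,
                                                       collapse = "")
            occupied[[i]] <- c(occupied[[i]], span)
            truth[[length(truth) + 1]] <- data.frame(
              promoter = names(seqs)[i], motif = iupac, position = pos,
              coord = -(L - pos + 1), stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!is.null(pm$position)) break
        }
        if (!placed && is.null(pm$position)) {
          stop("motif injection collision could not be resolved",
               call. = FALSE)
        }
      }
    }
  }
  list(promoters = promoter_set(seqs, target_length = L),
       truth = do.call(rbind, truth) %||%
         data.frame(promoter = character(0), motif = character(0),
                    position = integer(0), coord = integer(0)))
}

#' Simulate read-mapping hit tables with planted expression signal
#'
#' Per gene and library, read counts are Poisson with the true mean from
#' `expression_truth`; a `fail_frac` fraction of reads is drawn below the
#' standard length/identity filters (alignment <= 100 bp or identity <= 90)
#' and the rest above, so filtering removes a known fraction.
#'
#' @param recipe A `simulation_recipe` with non-NULL `expression_truth`
#'   (`gene_id`, `mean_a`, `mean_b`).
#' @param libraries Two library ids (default `c("leaf", "root")`).
#' @param seed Optional seed override.
#' @return List with `hits` (hit-record data.frame), `library_sizes`
#'   (set to 1e6 per library so CPM equals raw counts at these depths), and
#'   `truth` (`gene_id`, `mean_a`, `mean_b`, `label` with the intended
#'   enrichment call at ratio > 8).
#' @export
simulate_hits <- function(recipe, libraries = c("leaf", "root"),
                          seed = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  et <- recipe$expression_truth
  if (is.null(et) || nrow(et) == 0) stop("expression_truth is empty",
                                         call. = FALSE)
  set.seed(seed %||% recipe$seed)
  rows <- list()
  for (g in seq_len(nrow(et))) {
    for (li in 1:2) {
      mu <- et[[c("mean_a", "mean_b")[li]]][g]
      n_reads <- rpois(1, mu)
      if (n_reads == 0) next
      fails <- stats::runif(n_reads) < recipe$fail_frac
      lens <- ifelse(fails & stats::runif(n_reads) < 0.5,
                     sample(30:100, n_reads, replace = TRUE),
                     sample(101:300, n_reads, replace = TRUE))
      ids <- ifelse(fails & lens > 100,
                    stats::runif(n_reads, 70, 90),
                    stats::runif(n_reads, 90.01, 100))
      rows[[length(rows) + 1]] <- data.frame(
        read_id = sprintf("%s_%s_r%04d", libraries[li], et$gene_id[g],
                          seq_len(n_reads)),
        gene_id = et$gene_id[g], aln_length = lens, pct_identity = ids,
        library_id = libraries[li], stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows) %||%
    data.frame(read_id = character(0), gene_id = character(0),
               aln_length = integer(0), pct_identity = numeric(0),
               library_id = character(0))
  ratio <- (et$mean_a + 0.5) / (et$mean_b + 0.5)
  label <- rep("none", nrow(et))
  label[ratio > 8] <- libraries[1]
  label[1 / ratio > 8] <- libraries[2]
  list(hits = hits,
       library_sizes = setNames(c(1e6, 1e6), libraries),
       truth = data.frame(gene_id = et$gene_id, mean_a = et$mean_a,
                          mean_b = et$mean_b, label = label,
                          stringsAsFactors = FALSE))
}
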