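# Seeded generators for every pipeline input, with planted ground truth:
# known SNP cluster partition, planted differentially expressed genes
# with inverse-chi-square variance prior, planted genital-tract-specific
# genes, and controlled reviewer discordance. One seed governs all
# generators; each generator derives its own fixed substream offset so
# regenerating one input never perturbs the others.

#' Simulation configuration
#'
#' Defaults mirror the study design: 76 risk SNPs in 54 clusters
#' (merging at <1 Mb), two expression datasets of 10 FTE vs 10 HGSOC and
#' 24 FTE vs 11 HGSOC samples, 2000 probes with 141 planted
#' differentially expressed genes (logFC +/- 2, variances drawn from an
#' inverse-chi-square prior with d0 = 4, s0^2 = 0.05), 25 tissues with 28
#' planted genital-tract-specific genes, and a 0.2 reviewer discordance
#' rate.
#'
#' @param seed Integer seed for all generators.
#' @param cluster_sizes SNP count per planted cluster; the defaults sum
#'   to 76 over 54 clusters.
#' @param n_indels Number of SNPs emitted as indels (the rest are
#'   substitutions).
#' @param chroms,chrom_length Chromosome layout for SNP and gene placement.
#' @param flank,merge_threshold Interval-building constants (see
#'   [interval_config()]).
#' @param n_probes Number of probes per expression dataset.
#' @param frac_de Fraction of probes planted as differentially expressed.
#' @param logfc_effect Planted absolute log2 fold change.
#' @param d0,s0_sq Variance-prior parameters: per-probe true variances are
#'   drawn as `s0_sq * d0 / chisq(d0)`.
#' @param n1,n2 Length-2 vectors: FTE and HGSOC sample sizes for datasets
#'   A and B.
#' @param frac_de_in_blocks Fraction of planted DE genes whose coordinates
#'   fall inside a risk block (the rest are placed outside all blocks).
#' @param n_tissues Number of tissues per resource (4 targets + the rest).
#' @param n_target_specific Number of planted genital-tract-specific genes
#'   among the planted DE genes.
#' @param k Rank cutoff used when planting tissue specificity.
#' @param discordance_rate Probability that reviewer B's label differs
#'   from the truth.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cluster_sizes = c(rep(1L, 40L), rep(2L, 10L),
                                         rep(4L, 4L)),
                       n_indels = 6L,
                       chroms = paste0("chr", 1:22),
                       chrom_length = 1.2e8,
                       flank = 1e6, merge_threshold = 1e6,
                       n_probes = 2000L, frac_de = 141 / 2000,
                       logfc_effect = 2, d0 = 4, s0_sq = 0.05,
                       n1 = c(10L, 24L), n2 = c(10L, 11L),
                       frac_de_in_blocks = 1,
                       n_tissues = 25L, n_target_specific = 28L,
                       k = 2L, discordance_rate = 0.2) {
  stopifnot(seed == as.integer(seed), all(cluster_sizes >= 1L),
            n_indels >= 0L, frac_de >= 0, frac_de <= 1,
            length(n1) == 2L, length(n2) == 2L, all(n1 >= 2L),
            all(n2 >= 2L), discordance_rate >= 0, discordance_rate <= 1,
            n_tissues >= 4L + k, n_indels <= sum(cluster_sizes))
  structure(list(seed = as.integer(seed), cluster_sizes = cluster_sizes,
                 n_indels = n_indels, chroms = chroms,
                 chrom_length = chrom_length, flank = flank,
                 merge_threshold = merge_threshold, n_probes = n_probes,
                 frac_de = frac_de, logfc_effect = logfc_effect,
                 d0 = d0, s0_sq = s0_sq, n1 = n1, n2 = n2,
                 frac_de_in_blocks = frac_de_in_blocks,
                 n_tissues = n_tissues,
                 n_target_specific = n_target_specific, k = as.integer(k),
                 discordance_rate = discordance_rate),
            class = "sim_config")
}

#' Generate a risk-SNP panel with a known cluster partition
#'
#' Clusters are laid out round-robin over the chromosome layout.
#' Within a cluster, adjacent SNP gaps are drawn strictly below the merge
#' threshold; between clusters on the same chromosome the nearest-SNP gap
#' exceeds it, so [build_blocks()] recovers exactly one block per planted
#' cluster.
#'
#' @param cfg A [sim_config()].
#' @return List with `snps` (a `snp_table`) and `truth` (data.frame:
#'   rsid, cluster).
#' @export
gen_snp_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  n_clusters <- length(cfg$cluster_sizes)
  chrom_of <- cfg$chroms[((seq_len(n_clusters) - 1L) %% length(cfg$chroms)) + 1L]
  cursor <- stats::setNames(rep(2e6, length(cfg$chroms)), cfg$chroms)
  rsid <- character(0); chrom <- character(0); pos <- numeric(0)
  cluster <- integer(0)
  idx <- 0L
  for (i in seq_len(n_clusters)) {
    ch <- chrom_of[i]
    p <- cursor[[ch]] + round(stats::runif(1, 0, 5e5))
    for (j in seq_len(cfg$cluster_sizes[i])) {
      idx <- idx + 1L
      rsid <- c(rsid, sprintf("rs%06d", idx))
      chrom <- c(chrom, ch)
      pos <- c(pos, p)
      cluster <- c(cluster, i)
      if (j < cfg$cluster_sizes[i]) {
        # strictly below the merge threshold so the chain stays linked
        p <- p + round(stats::runif(1, 5e4, 0.95 * cfg$merge_threshold))
      }
    }
    # nearest-SNP gap to the next cluster strictly above the threshold
    cursor[[ch]] <- p + cfg$merge_threshold + round(stats::runif(1, 5e5, 3e6))
    if (cursor[[ch]] > cfg$chrom_length - 5e6) {
      stop("infeasible cluster spec: chromosome ", ch, " exhausted")
    }
  }
  n <- length(rsid)
  vclass <- rep("substitution", n)
  if (cfg$n_indels > 0L) {
    vclass[sample.int(n, cfg$n_indels)] <- "indel"
  }
  snps <- new_snp_table(data.frame(rsid = rsid, chrom = chrom, pos = pos,
                                   vclass = vclass, stringsAsFactors = FALSE))
  list(snps = snps, truth = data.frame(rsid = rsid, cluster = cluster,
                                       stringsAsFactors = FALSE))
}

#' Write a SNP table as BED
#'
#' Substitutions become single-base records (`start = pos - 1`,
#' `end = pos`); indels span two bases so the record class survives the
#' BED round trip.
#'
#' @param snps A `snp_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_snp_bed <- function(snps, path) {
  stopifnot(is.data.frame(snps))
  width <- ifelse(snps$vclass == "indel", 2L, 1L)
  lines <- sprintf("%s\t%d\t%d\t%s", snps$chrom,
                   as.integer(snps$pos) - 1L,
                   as.integer(snps$pos) - 1L + width, snps$rsid)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a pair of expression datasets with planted DE genes
#'
#' Per-probe true variances are drawn as `s0_sq * d0 / chisq(d0)`
#' independently per dataset; baseline probe means are Normal(7, 1) on
#' the log2 scale and shared. Planted DE probes are shifted in the HGSOC
#' group by `+/- logfc_effect` with the same sign in both datasets. Each
#' planted DE probe maps to its own gene; background probes are paired
#' two per gene. Gene coordinates place a configurable fraction of DE
#' genes inside the supplied blocks and every background gene outside all
#' blocks.
#'
#' @param cfg A [sim_config()].
#' @param blocks Optional blocks from [build_blocks()] used for gene
#'   placement; without them genes are placed uniformly on the layout.
#' @return List with `ds_a`, `ds_b` ([expression_dataset()]s), `annot`
#'   (annotation data.frame) and `truth` (data.frame: probe_id,
#'   gene_symbol, de, sign, in_block).
#' @export
gen_expression_pair <- function(cfg = sim_config(), blocks = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  n <- cfg$n_probes
  n_de <- round(cfg$frac_de * n)
  probe_id <- sprintf("probe_%05d", seq_len(n))
  de <- rep(FALSE, n)
  de[sample.int(n, n_de)] <- TRUE
  sign <- integer(n)
  sign[de] <- sample(c(-1L, 1L), n_de, replace = TRUE)

  mu <- stats::rnorm(n, mean = 7, sd = 1)
  make_ds <- function(n_fte, n_hgsoc, name) {
    sigma2 <- cfg$s0_sq * cfg$d0 / stats::rchisq(n, df = cfg$d0)
    ns <- n_fte + n_hgsoc
    m <- matrix(stats::rnorm(n * ns, mean = mu, sd = sqrt(sigma2)),
                nrow = n, ncol = ns)
    shift <- sign * cfg$logfc_effect
    m[, seq.int(n_fte + 1L, ns)] <- m[, seq.int(n_fte + 1L, ns)] + shift
    dimnames(m) <- list(probe_id, paste0(name, "_s", seq_len(ns)))
    expression_dataset(m, rep(c("FTE", "HGSOC"), c(n_fte, n_hgsoc)),
                       name = name)
  }
  ds_a <- make_ds(cfg$n1[1L], cfg$n2[1L], "dataset_A")
  ds_b <- make_ds(cfg$n1[2L], cfg$n2[2L], "dataset_B")

  # gene assignment: one gene per DE probe, background probes paired
  gene <- character(n)
  gene[de] <- sprintf("GENE_D%04d", seq_len(n_de))
  bg <- which(!de)
  gene[bg] <- sprintf("GENE_B%04d", ceiling(seq_along(bg) / 2))
  genes <- unique(gene)
  gene_de <- genes %in% gene[de]

  coords <- place_genes(genes, gene_de, cfg, blocks)
  annot <- data.frame(probe_id = probe_id, gene_symbol = gene,
                      stringsAsFactors = FALSE)
  annot <- merge(annot, coords, by = "gene_symbol", sort = FALSE)
  annot <- validate_annotation(
    annot[order(annot$probe_id),
          c("probe_id", "gene_symbol", "chrom", "gene_start", "gene_end")])
  truth <- data.frame(probe_id = probe_id, gene_symbol = gene, de = de,
                      sign = sign, stringsAsFactors = FALSE)
  truth$in_block <- coords$in_block[match(truth$gene_symbol,
                                          coords$gene_symbol)]
  list(ds_a = ds_a, ds_b = ds_b, annot = annot, truth = truth)
}

# Place genes on the chromosome layout. DE genes: a fraction
# frac_de_in_blocks inside a random block, the rest outside; background
# genes always outside all blocks (so planted DE genes alone can satisfy
# the block-overlap filter).
place_genes <- function(genes, is_de, cfg, blocks) {
  n <- length(genes)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  in_block <- logical(n)
  gaps <- block_free_regions(cfg, blocks)
  de_idx <- which(is_de)
  n_in <- round(cfg$frac_de_in_blocks * length(de_idx))
  put_in_block <- rep(FALSE, n)
  if (!is.null(blocks) && length(de_idx) > 0L && n_in > 0L) {
    put_in_block[de_idx[seq_len(n_in)]] <- TRUE
  }
  for (i in seq_len(n)) {
    w <- round(stats::runif(1, 1e4, 8e4))
    if (put_in_block[i]) {
      b <- blocks[sample.int(nrow(blocks), 1L), ]
      s <- round(stats::runif(1, b$start, b$end - w))
      chrom[i] <- b$chrom
      in_block[i] <- TRUE
    } else {
      g <- gaps[sample.int(nrow(gaps), 1L, prob = gaps$len), ]
      s <- round(stats::runif(1, g$start, g$end - w))
      chrom[i] <- g$chrom
    }
    start[i] <- s
    end[i] <- s + w
  }
  data.frame(gene_symbol = genes, chrom = chrom, gene_start = start,
             gene_end = end, in_block = in_block, stringsAsFactors = FALSE)
}

# Intervals of the layout not covered by any block (with a safety margin),
# used to place background genes.
block_free_regions <- function(cfg, blocks, margin = 1e5, min_len = 5e5) {
  out <- list()
  for (ch in cfg$chroms) {
    b <- if (is.null(blocks)) NULL else
      blocks[blocks$chrom == ch, , drop = FALSE]
    if (is.null(b) || nrow(b) == 0L) {
      out[[ch]] <- data.frame(chrom = ch, start = 1, end = cfg$chrom_length)
      next
    }
    b <- b[order(b$start), ]
    # merge overlapping blocks into covered runs
    cs <- b$start[1L]; ce <- b$end[1L]; runs <- list()
    for (i in seq_len(nrow(b))[-1L]) {
      if (b$start[i] <= ce) ce <- max(ce, b$end[i]) else {
        runs[[length(runs) + 1L]] <- c(cs, ce); cs <- b$start[i]; ce <- b$end[i]
      }
    }
    runs[[length(runs) + 1L]] <- c(cs, ce)
    bounds <- c(1, unlist(runs), cfg$chrom_length)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- (ends - margin) - (starts + margin) >= min_len
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] + margin,
                              end = ends[keep] - margin)
    }
  }
  gaps <- do.call(rbind, out)
  gaps$len <- gaps$end - gaps$start
  rownames(gaps) <- NULL
  gaps
}

#' Built-in tissue panel for the synthetic resources
#'
#' Four female genital-tract target tissues plus common somatic tissues,
#' truncated to `n_tissues`.
#'
#' @param n_tissues Panel size (targets always included).
#' @return Character vector of tissue names.
#' @export
sim_tissue_panel <- function(n_tissues = 25L) {
  targets <- c("cervix", "endometrium", "fallopian tube", "ovary")
  others <- c("adipose tissue", "adrenal gland", "bladder", "brain",
              "breast", "colon", "duodenum", "esophagus", "heart",
              "kidney", "liver", "lung", "pancreas", "prostate",
              "salivary gland", "skeletal muscle", "skin",
              "small intestine", "spleen", "stomach", "testis")
  stopifnot(n_tissues >= length(targets) + 1L,
            n_tissues <= length(targets) + length(others))
  c(targets, others[seq_len(n_tissues - length(targets))])
}

#' Generate two gene x tissue tables with planted specific genes
#'
#' Planted genital-tract-specific genes get a target tissue as the row
#' maximum in both resources. Every background gene is constructed to
#' fail the top-k criterion in at least one resource: its target tissues
#' are suppressed and at least `k` non-target tissues are raised above
#' them there.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene symbols to tabulate.
#' @param specific_genes Genes to plant as genital-tract specific; by
#'   default `n_target_specific` genes sampled from `genes`.
#' @return List with `tab_a`, `tab_b` (matrices), `cfg_rank` (a matching
#'   [rank_config()]) and `truth` (the planted specific gene set).
#' @export
gen_tissue_tables <- function(cfg = sim_config(), genes,
                              specific_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(genes) >= 1L)
  set.seed(cfg$seed + 303L)
  tissues <- sim_tissue_panel(cfg$n_tissues)
  targets <- c("cervix", "endometrium", "fallopian tube", "ovary")
  non_targets <- setdiff(tissues, targets)
  if (is.null(specific_genes)) {
    stopifnot(cfg$n_target_specific <= length(genes))
    specific_genes <- sample(genes, cfg$n_target_specific)
  }
  stopifnot(all(specific_genes %in% genes))
  make_row <- function(specific, fail_here) {
    row <- stats::setNames(stats::rlnorm(length(tissues), 2, 1), tissues)
    if (specific) {
      t <- sample(targets, 1L)
      row[t] <- max(row) * stats::runif(1, 1.3, 2.5)
    } else if (fail_here) {
      row[targets] <- row[targets] * 0.05
      top <- sample(non_targets, cfg$k)
      row[top] <- max(row) * stats::runif(cfg$k, 1.5, 2)
    }
    row
  }
  n <- length(genes)
  tab_a <- matrix(0, n, length(tissues), dimnames = list(genes, tissues))
  tab_b <- matrix(0, n, length(tissues), dimnames = list(genes, tissues))
  for (i in seq_len(n)) {
    sp <- genes[i] %in% specific_genes
    fail_in <- if (sp) 0L else sample(1:2, 1L)
    tab_a[i, ] <- make_row(sp, fail_in == 1L)
    tab_b[i, ] <- make_row(sp, fail_in == 2L)
  }
  attr(tab_a, "resource") <- "GTEx-like"
  attr(tab_b, "resource") <- "HPA-like"
  list(tab_a = tab_a, tab_b = tab_b,
       cfg_rank = rank_config(tissues, targets, cfg$k),
       truth = sort(specific_genes))
}

#' Generate two-reviewer localization labels with controlled discordance
#'
#' Reviewer A reports the truth; reviewer B flips each gene's label to a
#' uniformly random other class with probability `discordance_rate`.
#' Every flipped gene receives an adjudication equal to the truth, so
#' consensus always recovers the true classes.
#'
#' @param cfg A [sim_config()].
#' @param true_classes Data.frame with `gene_symbol` and `class`.
#' @return List with `a`, `b`, `adjudications` (data.frames) and
#'   `truth` (= `true_classes`).
#' @export
gen_reviewer_labels <- function(cfg = sim_config(), true_classes) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(true_classes),
            all(true_classes$class %in% localization_classes()))
  set.seed(cfg$seed + 404L)
  n <- nrow(true_classes)
  flip <- stats::runif(n) < cfg$discordance_rate
  b_class <- true_classes$class
  for (i in which(flip)) {
    b_class[i] <- sample(setdiff(localization_classes(),
                                 true_classes$class[i]), 1L)
  }
  list(
    a = data.frame(gene_symbol = true_classes$gene_symbol,
                   class = true_classes$class, stringsAsFactors = FALSE),
    b = data.frame(gene_symbol = true_classes$gene_symbol,
                   class = b_class, stringsAsFactors = FALSE),
    adjudications = data.frame(
      gene_symbol = true_classes$gene_symbol[flip],
      class = true_classes$class[flip], stringsAsFactors = FALSE),
    truth = true_classes
  )
}

#' Draw true localization classes mirroring the study composition
#'
#' Deals classes in the observed shortlist proportions (11/28 ambiguous,
#' 3/28 not available, 1/28 not detected, 7/28 ciliated, 3/28 ciliated
#' subset, 2/28 ciliated and serous, 1/28 serous), shuffled over the
#' genes.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene symbols.
#' @return Data.frame with `gene_symbol` and `class`.
#' @export
gen_true_classes <- function(cfg = sim_config(), genes) {
  set.seed(cfg$seed + 505L)
  comp <- c(ambiguous = 11, not_available = 3, not_expressed = 1,
            ciliated = 7, ciliated_subset = 3, ciliated_and_serous = 2,
            serous = 1)
  n <- length(genes)
  counts <- floor(comp / sum(comp) * n)
  while (sum(counts) < n) {
    i <- which.max(comp / sum(comp) * n - counts)
    counts[i] <- counts[i] + 1
  }
  cls <- sample(rep(names(counts), counts))
  data.frame(gene_symbol = genes, class = cls, stringsAsFactors = FALSE)
}

#' Write every pipeline input to a directory
#'
#' Emits, under `outdir`: `snps.bed`, `expr_a.tsv` + `groups_a.tsv`,
#' `expr_b.tsv` + `groups_b.tsv`, `annot.tsv`, `tissue_a.tsv`,
#' `tissue_b.tsv`, `ihc_labels.tsv` and `truth.json`, all derived from a
#' single seeded configuration and in the exact formats the readers
#' consume.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths), `truth`
#'   (per-stage ground truth) and `tissues` (the shared tissue panel).
#' @export
simulate_inputs <- function(cfg = sim_config(), outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)

  panel <- gen_snp_panel(cfg)
  write_snp_bed(panel$snps, pth("snps.bed"))
  blocks <- build_blocks(panel$snps,
                         interval_config(cfg$flank, cfg$merge_threshold))
  expr <- gen_expression_pair(cfg, blocks)
  write_expression <- function(ds, mfile, gfile) {
    tab <- data.frame(probe_id = rownames(ds$matrix), ds$matrix,
                      check.names = FALSE)
    utils::write.table(tab, pth(mfile), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample = colnames(ds$matrix),
                 group = as.character(ds$groups)),
      pth(gfile), sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  write_expression(expr$ds_a, "expr_a.tsv", "groups_a.tsv")
  write_expression(expr$ds_b, "expr_b.tsv", "groups_b.tsv")
  utils::write.table(expr$annot, pth("annot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  all_genes <- unique(expr$annot$gene_symbol)
  de_genes <- unique(expr$truth$gene_symbol[expr$truth$de])
  set.seed(cfg$seed + 606L)
  tis <- gen_tissue_tables(cfg, all_genes,
                           specific_genes = sample(de_genes,
                                                   min(cfg$n_target_specific,
                                                       length(de_genes))))
  write_tissue <- function(tab, file) {
    utils::write.table(
      data.frame(gene_symbol = rownames(tab), tab, check.names = FALSE),
      pth(file), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tissue(tis$tab_a, "tissue_a.tsv")
  write_tissue(tis$tab_b, "tissue_b.tsv")

  true_cls <- gen_true_classes(cfg, tis$truth)
  rev <- gen_reviewer_labels(cfg, true_cls)
  adj <- rep(NA_character_, nrow(true_cls))
  adj[match(rev$adjudications$gene_symbol, true_cls$gene_symbol)] <-
    rev$adjudications$class
  utils::write.table(
    data.frame(gene_symbol = rev$a$gene_symbol, reviewer_a = rev$a$class,
               reviewer_b = rev$b$class, adjudication = adj),
    pth("ihc_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    snp_clusters = panel$truth, n_clusters = length(cfg$cluster_sizes),
    blocks = blocks, de = expr$truth, specific_genes = tis$truth,
    true_classes = true_cls
  )
  jsonlite::write_json(
    list(n_clusters = length(cfg$cluster_sizes),
         n_de_genes = length(de_genes),
         specific_genes = tis$truth),
    pth("truth.json"), auto_unbox = TRUE)
  invisible(list(
    files = c(snps = pth("snps.bed"), expr_a = pth("expr_a.tsv"),
              groups_a = pth("groups_a.tsv"), expr_b = pth("expr_b.tsv"),
              groups_b = pth("groups_b.tsv"), annot = pth("annot.tsv"),
              tissue_a = pth("tissue_a.tsv"), tissue_b = pth("tissue_b.tsv"),
              ihc = pth("ihc_labels.tsv")),
    truth = truth, tissues = sim_tissue_panel(cfg$n_tissues)
  ))
}
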