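# Orchestrates the five stages into one reproducible run:
# blocks -> DE x2 -> concordance -> block overlap -> tissue-rank filter
# -> localization summary, with a machine-readable funnel report.

#' Default pipeline thresholds
#'
#' The study's constants: 1 Mb flank, <1 Mb merge, r^2 >= 0.5 for LD
#' proxies, adjusted p < 0.05, |logFC| > 1, tissue rank cutoff k = 2.
#' Every value can be overridden through the run config; the effective
#' values are echoed in the report.
#'
#' @return Named list of threshold defaults.
#' @export
default_thresholds <- function() {
  list(flank = 1e6, merge_lt = 1e6, r2_min = 0.5, alpha_q = 0.05,
       min_abs_logfc = 1.0, k = 2L,
       target_tissues = c("cervix", "endometrium", "fallopian tube",
                          "ovary"),
       de_method = "moderated")
}

#' Run the full prioritization pipeline
#'
#' Executes the stages in order — interval building, differential
#' expression on both datasets, cross-dataset concordance, block overlap,
#' tissue-specificity filtering, localization consensus — each skippable,
#' writes every stage output plus a JSON funnel report under
#' `config$outdir`, and returns the report. Rerunning with identical
#' inputs and config reproduces identical outputs: the pipeline proper
#' contains no randomness.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised elements: `inputs` (paths `snps`, `ld`, `expr_a`,
#'   `groups_a`, `expr_b`, `groups_b`, `annot`, `tissue_a`, `tissue_b`,
#'   `ihc`, `table1`), `tissues` (shared tissue names), `thresholds`
#'   (overrides of [default_thresholds()]), `stages` (subset of
#'   `c("blocks", "de", "overlap", "rankfilter", "ihc")`, default all
#'   runnable), `total_blocks` (denominator override for the block
#'   percentage), `outdir`.
#' @return A list of class `funnel_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  th <- utils::modifyList(default_thresholds(),
                          config$thresholds %||% list())
  inputs <- config$inputs %||% list()
  stages <- config$stages %||% c("blocks", "de", "overlap", "rankfilter",
                                 "ihc")
  outdir <- config$outdir %||% tempfile("cilioprior_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  report <- list(
    tool = "cilioprior",
    version = as.character(utils::packageVersion("cilioprior")),
    thresholds = th,
    stages = stages,
    counts = list(),
    input_digests = input_digests(inputs)
  )
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  blocks <- NULL
  if ("blocks" %in% stages) {
    blocks <- stage_err("blocks", {
      snps <- read_snp_bed(inputs$snps)
      b <- build_blocks(snps, interval_config(th$flank, th$merge_lt))
      report$counts$n_snps <- nrow(snps)
      report$counts$n_blocks <- nrow(b)
      write_blocks_bed(b, file.path(outdir, "blocks.bed"))
      if (!is.null(inputs$ld)) {
        ld <- check_ld_containment(b, read_ld_tsv(inputs$ld), th$r2_min)
        report$counts$n_ld_proxies_checked <- nrow(ld)
        report$counts$n_ld_violations <- attr(ld, "n_violations")
      }
      b
    })
  }

  concord <- NULL
  if ("de" %in% stages) {
    concord <- stage_err("de", {
      dsa <- read_expression_tsv(inputs$expr_a, inputs$groups_a,
                                 name = config$name_a %||% "dataset_A")
      dsb <- read_expression_tsv(inputs$expr_b, inputs$groups_b,
                                 name = config$name_b %||% "dataset_B")
      dethr <- de_thresholds(th$alpha_q, th$min_abs_logfc)
      res_a <- de_results(fit_moderated_t(dsa, method = th$de_method))
      res_b <- de_results(fit_moderated_t(dsb, method = th$de_method))
      sig_a <- apply_thresholds(res_a, dethr)
      sig_b <- apply_thresholds(res_b, dethr)
      cc <- concordant_probes(sig_a, sig_b)
      report$counts$n_significant_a <- nrow(sig_a)
      report$counts$n_significant_b <- nrow(sig_b)
      report$counts$n_concordant <- nrow(cc)
      write_tsv <- function(x, f) utils::write.table(
        x, file.path(outdir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
      write_tsv(res_a, "de_a.tsv"); write_tsv(res_b, "de_b.tsv")
      write_tsv(cc, "concordant.tsv")
      cc
    })
  }

  candidates <- NULL
  if ("overlap" %in% stages) {
    if (is.null(blocks) || is.null(concord)) {
      stop("pipeline stage 'overlap' failed: requires the blocks and de ",
           "stages", call. = FALSE)
    }
    candidates <- stage_err("overlap", {
      annot <- read_annotation_tsv(inputs$annot)
      hits <- assign_to_blocks(concord, annot, blocks)
      cand <- dedupe_by_gene(hits)
      report$counts$n_block_resident_probes <- length(unique(hits$probe_id))
      report$counts$n_candidate_genes <- length(unique(cand$gene_symbol))
      utils::write.table(cand, file.path(outdir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cand
    })
  }

  shortlist <- NULL
  if ("rankfilter" %in% stages) {
    if (is.null(candidates)) {
      stop("pipeline stage 'rankfilter' failed: requires the overlap ",
           "stage", call. = FALSE)
    }
    shortlist <- stage_err("rankfilter", {
      tab_a <- read_tissue_tsv(inputs$tissue_a)
      tab_b <- read_tissue_tsv(inputs$tissue_b)
      tissues <- config$tissues %||%
        intersect(colnames(tab_a), colnames(tab_b))
      rcfg <- rank_config(tissues, th$target_tissues, th$k)
      sl <- specificity_filter(unique(candidates$gene_symbol),
                               tab_a, tab_b, rcfg)
      report$counts$n_shortlist <- length(sl)
      report$counts$n_rankfilter_dropped <- length(attr(sl, "dropped"))
      utils::write.table(attr(sl, "report"),
                         file.path(outdir, "shortlist_ranks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(as.character(sl), file.path(outdir, "shortlist.tsv"))
      sl
    })
  }

  if ("ihc" %in% stages) {
    summ <- stage_err("ihc", {
      total_blocks <- config$total_blocks %||% report$counts$n_blocks
      if (is.null(total_blocks)) {
        stop("ihc stage needs total_blocks (or a prior blocks stage)")
      }
      if (!is.null(inputs$table1)) {
        t1 <- read_table1(inputs$table1)
        records <- data.frame(gene_symbol = t1$gene_symbol,
                              class = t1$class,
                              block_label = t1$block_label,
                              stringsAsFactors = FALSE)
      } else {
        labs <- read_reviewer_tsv(inputs$ihc)
        if (!is.null(shortlist)) {
          keep <- labs$a$gene_symbol %in% as.character(shortlist)
          labs$a <- labs$a[keep, , drop = FALSE]
          labs$b <- labs$b[labs$b$gene_symbol %in% as.character(shortlist), ,
                           drop = FALSE]
          labs$adjudications <- labs$adjudications[
            labs$adjudications$gene_symbol %in% as.character(shortlist), ,
            drop = FALSE]
        }
        records <- consensus_merge(labs$a, labs$b, labs$adjudications)
        if (!is.null(candidates)) {
          records$block_label <- candidates$block_label[
            match(records$gene_symbol, candidates$gene_symbol)]
        }
      }
      s <- summarize_localization(records, total_blocks)
      jsonlite::write_json(unclass(s), file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      s
    })
    report$counts$localization <- unclass(summ)
  }

  report$outdir <- outdir
  class(report) <- "funnel_report"
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report
}

input_digests <- function(inputs) {
  paths <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && length(x) == 1L && file.exists(x), logical(1L))])
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.funnel_report <- function(x, ...) {
  cat("cilioprior funnel report (v", x$version, ")\n", sep = "")
  cnt <- x$counts
  show <- function(lab, v) if (!is.null(v)) cat(sprintf("  %-28s %s\n", lab, v))
  show("input SNPs:", cnt$n_snps)
  show("merged blocks:", cnt$n_blocks)
  show("significant probes (A):", cnt$n_significant_a)
  show("significant probes (B):", cnt$n_significant_b)
  show("concordant probes:", cnt$n_concordant)
  show("block-resident genes:", cnt$n_candidate_genes)
  show("tissue-specific shortlist:", cnt$n_shortlist)
  if (!is.null(cnt$localization)) {
    loc <- cnt$localization
    cat(sprintf("  localization: %d genes, %d ciliated-positive in %d/%d blocks (%d%%)\n",
                loc$n_genes, loc$n_ciliated_positive,
                loc$n_distinct_blocks_ciliated, loc$total_blocks,
                loc$pct_blocks_ciliated))
  }
  cat("  outputs in:", x$outdir, "\n")
  invisible(x)
}
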