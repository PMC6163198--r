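# Merged candidate genomic blocks around risk SNPs, and LD-proxy
# containment checks.

#' Interval-building configuration
#'
#' Defaults encode the study design: a 2-Mb window per risk SNP (1 Mb
#' upstream, 1 Mb downstream) and single-linkage grouping of SNPs less
#' than 1 Mb apart (strict inequality).
#'
#' @param flank Bases added on each side of the SNP cluster (default 1e6).
#' @param merge_threshold SNPs strictly closer than this merge (default 1e6).
#' @param label_prefix Prefix for block labels.
#' @return A list of class `interval_config`.
#' @export
interval_config <- function(flank = 1e6, merge_threshold = 1e6,
                            label_prefix = "GWAS_EOC_") {
  stopifnot(flank > 0, merge_threshold > 0, is.character(label_prefix))
  structure(list(flank = flank, merge_threshold = merge_threshold,
                 label_prefix = label_prefix),
            class = "interval_config")
}

#' Build merged genomic blocks around risk SNPs
#'
#' Per chromosome, SNPs are grouped by single-linkage under the relation
#' |pos_i - pos_j| < merge_threshold (strict): any chain of SNPs with
#' adjacent gaps below the threshold forms one group. Each group becomes
#' one block spanning `min(pos) - flank` to `max(pos) + flank` (1-based
#' inclusive; the start is floored at 1 with a warning). Blocks are
#' labelled `label_prefix + ordinal` after sorting by (chromosome
#' lexicographic, start). Blocks from distinct groups may overlap: groups
#' merge only through the SNP-distance rule, never through block overlap.
#'
#' @param snps A `snp_table` from [read_snp_bed()] (or any data.frame with
#'   `rsid`, `chrom`, `pos`).
#' @param cfg An [interval_config()].
#' @return A data.frame of class `genomic_blocks` with columns `label`,
#'   `chrom`, `start`, `end`, `n_snps` and a list-column `member_snps`.
#' @examples
#' snps <- data.frame(rsid = c("rs1", "rs2"), chrom = "chr2",
#'                    pos = c(10e6, 10.5e6))
#' build_blocks(snps, interval_config())
#' @export
build_blocks <- function(snps, cfg = interval_config()) {
  stopifnot(inherits(cfg, "interval_config"), is.data.frame(snps))
  if (nrow(snps) == 0L) stop("cannot build blocks from an empty SNP table")
  blocks <- list()
  for (ch in sort(unique(snps$chrom))) {
    sub <- snps[snps$chrom == ch, , drop = FALSE]
    ord <- order(sub$pos, sub$rsid)
    sub <- sub[ord, , drop = FALSE]
    gap <- diff(sub$pos)
    # new group wherever the adjacent gap reaches the threshold (strict <
    # merges, so >= splits); single-linkage closure on sorted positions
    grp <- cumsum(c(1L, as.integer(gap >= cfg$merge_threshold)))
    for (g in split(seq_len(nrow(sub)), grp)) {
      blocks[[length(blocks) + 1L]] <- list(
        chrom = ch,
        start = min(sub$pos[g]) - cfg$flank,
        end = max(sub$pos[g]) + cfg$flank,
        member_snps = sub$rsid[g]
      )
    }
  }
  chrom <- vapply(blocks, `[[`, "", "chrom")
  start <- vapply(blocks, `[[`, 0, "start")
  end <- vapply(blocks, `[[`, 0, "end")
  if (any(start < 1)) {
    warning(sum(start < 1), " block start(s) clamped to 1")
    start <- pmax(start, 1)
  }
  ord <- order(chrom, start)
  out <- data.frame(
    label = paste0(cfg$label_prefix, seq_along(ord)),
    chrom = chrom[ord], start = start[ord], end = end[ord],
    n_snps = lengths(lapply(blocks, `[[`, "member_snps"))[ord],
    stringsAsFactors = FALSE
  )
  out$member_snps <- lapply(blocks, `[[`, "member_snps")[ord]
  attr(out, "config") <- cfg
  class(out) <- c("genomic_blocks", "data.frame")
  out
}

#' @export
print.genomic_blocks <- function(x, ...) {
  cat(nrow(x), "genomic block(s) covering", sum(x$n_snps), "SNP(s)\n")
  print.data.frame(utils::head(x[c("label", "chrom", "start", "end",
                                   "n_snps")], 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Check that LD proxies fall inside their index SNP's block
#'
#' A proxy with r-squared at or above `r2_min` is "contained" if its
#' position lies within the block whose member list holds its index SNP
#' (same chromosome, position within [start, end]); otherwise it is a
#' violation. Proxies below `r2_min` are ignored.
#'
#' @param blocks Blocks from [build_blocks()].
#' @param proxies LD proxy table from [read_ld_tsv()].
#' @param r2_min Minimum r-squared for a proxy to be checked (default 0.5).
#' @return A data.frame (one row per checked proxy) with columns
#'   `index_rsid`, `proxy_rsid`, `block_label`, `contained`; the number of
#'   violations is in attribute `n_violations`.
#' @export
check_ld_containment <- function(blocks, proxies, r2_min = 0.5) {
  stopifnot(is.data.frame(blocks), is.data.frame(proxies))
  snp2block <- rep(blocks$label, lengths(blocks$member_snps))
  names(snp2block) <- unlist(blocks$member_snps)
  unknown <- setdiff(unique(proxies$index_rsid), names(snp2block))
  if (length(unknown) > 0L) {
    stop("index rsid(s) not found in any block: ",
         paste(unknown, collapse = ", "))
  }
  px <- proxies[proxies$r2 >= r2_min, , drop = FALSE]
  if (nrow(px) == 0L) {
    out <- data.frame(index_rsid = character(), proxy_rsid = character(),
                      block_label = character(), contained = logical())
    attr(out, "n_violations") <- 0L
    return(out)
  }
  lab <- snp2block[px$index_rsid]
  idx <- match(lab, blocks$label)
  contained <- blocks$chrom[idx] == px$chrom &
    px$pos >= blocks$start[idx] & px$pos <= blocks$end[idx]
  out <- data.frame(index_rsid = px$index_rsid, proxy_rsid = px$proxy_rsid,
                    block_label = unname(lab), contained = contained,
                    stringsAsFactors = FALSE)
  attr(out, "n_violations") <- sum(!contained)
  out
}
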