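# Intersect concordant differentially expressed genes with the candidate
# blocks. Overlap rule: any-base overlap of the full annotated gene span
# with the block (1-based inclusive intervals on both sides).

#' Assign concordant probes to genomic blocks
#'
#' Joins the concordant probe set to its gene annotation and emits one
#' candidate hit per (probe, block) pair whose gene span overlaps the
#' block by at least one base. A gene overlapping two (possibly mutually
#' overlapping) blocks yields two hits. Probes without an annotation row
#' are excluded with a warning and listed in the `excluded` attribute.
#'
#' @param concordant Concordant probe set from [concordant_probes()].
#' @param annot Annotation table from [read_annotation_tsv()].
#' @param blocks Blocks from [build_blocks()].
#' @return Data.frame of candidate hits: probe_id, gene_symbol,
#'   block_label, chrom, gene_start, gene_end, direction, logFC_a,
#'   logFC_b, q_a, q_b.
#' @export
assign_to_blocks <- function(concordant, annot, blocks) {
  stopifnot(is.data.frame(concordant), is.data.frame(annot),
            is.data.frame(blocks))
  empty <- data.frame(probe_id = character(), gene_symbol = character(),
                      block_label = character(), chrom = character(),
                      gene_start = numeric(), gene_end = numeric(),
                      direction = numeric(), logFC_a = numeric(),
                      logFC_b = numeric(), q_a = numeric(), q_b = numeric(),
                      stringsAsFactors = FALSE)
  unannotated <- setdiff(concordant$probe_id, annot$probe_id)
  if (length(unannotated) > 0L) {
    warning(length(unannotated), " probe(s) without annotation excluded")
  }
  hit_rows <- merge(concordant, annot, by = "probe_id")
  if (nrow(hit_rows) == 0L) {
    attr(empty, "excluded") <- unannotated
    return(empty)
  }
  genes <- GenomicRanges::GRanges(
    hit_rows$chrom,
    IRanges::IRanges(hit_rows$gene_start, hit_rows$gene_end))
  blk <- GenomicRanges::GRanges(
    blocks$chrom, IRanges::IRanges(blocks$start, blocks$end))
  ov <- GenomicRanges::findOverlaps(genes, blk, minoverlap = 1L)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    probe_id = hit_rows$probe_id[qi],
    gene_symbol = hit_rows$gene_symbol[qi],
    block_label = blocks$label[si],
    chrom = hit_rows$chrom[qi],
    gene_start = hit_rows$gene_start[qi],
    gene_end = hit_rows$gene_end[qi],
    direction = hit_rows$direction[qi],
    logFC_a = hit_rows$logFC_a[qi],
    logFC_b = hit_rows$logFC_b[qi],
    q_a = hit_rows$q_a[qi],
    q_b = hit_rows$q_b[qi],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$block_label, out$gene_symbol, out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- unannotated
  out
}

#' Collapse candidate hits to one record per gene and block
#'
#' Keeps one representative probe per (gene_symbol, block_label): the
#' probe with the smallest adjusted p in dataset A, ties broken by larger
#' |logFC| in dataset A, then by lexicographic probe id. A gene
#' overlapping two blocks keeps one record per block.
#'
#' @param hits Candidate hits from [assign_to_blocks()].
#' @return Gene-level candidate data.frame, one row per (gene, block).
#' @export
dedupe_by_gene <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    out <- hits
    rownames(out) <- NULL
    return(out)
  }
  key <- paste(hits$gene_symbol, hits$block_label, sep = "\r")
  picked <- vapply(split(seq_len(nrow(hits)), key), function(idx) {
    sub <- hits[idx, , drop = FALSE]
    ord <- order(sub$q_a, -abs(sub$logFC_a), sub$probe_id)
    idx[ord[1L]]
  }, integer(1L))
  out <- hits[sort(unname(picked)), , drop = FALSE]
  out <- out[order(out$block_label, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
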