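# Readers/writers for every external table the pipeline touches.
# Internal coordinates are 1-based inclusive everywhere; BED conversion
# happens only here, at the I/O boundary.

#' Read a BED file of risk SNPs
#'
#' Parses a BED file of GWAS risk variants into a SNP table. BED intervals
#' are half-open and 0-based; the 1-based position of a variant is taken as
#' `start + 1`, i.e. the first affected base (also for indels). Records
#' spanning a single base are classed as nucleotide substitutions, records
#' spanning more than one base as indels; an optional sixth column may
#' override the class with the literal strings `"substitution"` or
#' `"indel"`.
#'
#' @param path Path to a BED file with at least four whitespace-separated
#'   columns: chrom, start (0-based), end, name (rsid).
#' @return A `data.frame` of class `snp_table` with columns `rsid`,
#'   `chrom`, `pos` (1-based), `vclass` (`"substitution"` or `"indel"`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t4999999\t5000000\trs1", "chr2\t100\t104\trs2\t0\tindel"), bed)
#' read_snp_bed(bed)
#' @export
read_snp_bed <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty BED file: ", path)
    return(new_snp_table(data.frame(
      rsid = character(), chrom = character(),
      pos = integer(), vclass = character(),
      stringsAsFactors = FALSE
    )))
  }
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed BED line ", which(nf < 4L)[1L],
         ": fewer than 4 fields in ", path)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": non-numeric coordinates in ", path)
  }
  if (any(end <= start)) {
    stop("invalid BED record at line ", which(end <= start)[1L],
         ": end <= start")
  }
  rsid <- vapply(fields, `[[`, "", 4L)
  vclass <- ifelse(end - start > 1, "indel", "substitution")
  has6 <- nf >= 6L
  if (any(has6)) {
    flag <- rep(NA_character_, length(fields))
    flag[has6] <- vapply(fields[has6], `[[`, "", 6L)
    use <- !is.na(flag) & flag %in% c("substitution", "indel")
    vclass[use] <- flag[use]
  }
  new_snp_table(data.frame(
    rsid = rsid, chrom = vapply(fields, `[[`, "", 1L),
    pos = start + 1, vclass = vclass,
    stringsAsFactors = FALSE
  ))
}

new_snp_table <- function(df) {
  if (anyDuplicated(df$rsid)) {
    stop("duplicate rsid(s): ",
         paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
  }
  if (any(df$pos < 1)) stop("SNP position < 1")
  if (any(!df$vclass %in% c("substitution", "indel"))) {
    stop("vclass must be 'substitution' or 'indel'")
  }
  rownames(df) <- NULL
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Write merged genomic blocks as BED
#'
#' Blocks are held internally as 1-based inclusive intervals; on disk they
#' become standard 0-based half-open BED (`start - 1`, `end`), sorted by
#' chromosome (lexicographic) then start, with the block label in the name
#' column.
#'
#' @param blocks A `genomic_blocks` data.frame from [build_blocks()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @seealso [read_blocks_bed()]
#' @export
write_blocks_bed <- function(blocks, path) {
  stopifnot(is.data.frame(blocks))
  if (nrow(blocks) == 0L) stop("refusing to write an empty block list")
  ord <- order(blocks$chrom, blocks$start)
  b <- blocks[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", b$chrom, as.integer(b$start) - 1L,
                   as.integer(b$end), b$label)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) stop("cannot write blocks BED to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read genomic blocks back from BED
#'
#' Inverse of [write_blocks_bed()]: converts 0-based half-open BED records
#' back to 1-based inclusive intervals. Member SNP lists are not stored in
#' BED and are absent from the result.
#'
#' @param path Path to a BED file written by [write_blocks_bed()].
#' @return A data.frame with columns `label`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_blocks_bed <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start0", "end", "label"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  data.frame(label = tab$label, chrom = tab$chrom,
             start = tab$start0 + 1, end = tab$end,
             stringsAsFactors = FALSE)
}

#' Read a log2 expression matrix with FTE/HGSOC group labels
#'
#' The matrix file is TSV with probe ids in the first column and sample ids
#' in the header. Groups are supplied either as a two-column TSV
#' (sample, group) or as a named character vector; every sample must be
#' labelled `"FTE"` or `"HGSOC"`. Probe rows containing any missing value
#' are dropped and their count reported, so downstream testing sees finite
#' values only.
#'
#' @param path Path to the expression TSV (log2 scale, probes x samples).
#' @param groups Path to a sample-to-group TSV, or a named character vector
#'   mapping sample id to group.
#' @param name Dataset name carried through reports.
#' @return An `expression_dataset`: list with `matrix` (numeric,
#'   probes x samples), `groups` (factor, levels FTE/HGSOC), `name`,
#'   `n_dropped` (probe rows removed for missingness).
#' @export
read_expression_tsv <- function(path, groups, name = basename(path)) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("non-numeric cell(s) in expression matrix ", path)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gtab <- utils::read.table(groups, sep = "\t", header = FALSE,
                              col.names = c("sample", "group"),
                              colClasses = "character")
    groups <- stats::setNames(gtab$group, gtab$sample)
  }
  if (is.null(names(groups))) stop("groups must be named by sample id")
  missing_samples <- setdiff(colnames(mat), names(groups))
  if (length(missing_samples) > 0L) {
    stop("sample(s) without a group label: ",
         paste(missing_samples, collapse = ", "))
  }
  absent <- setdiff(names(groups), colnames(mat))
  if (length(absent) > 0L) {
    stop("group file names sample(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  }
  expression_dataset(mat, groups[colnames(mat)], name = name)
}

#' Construct an expression dataset
#'
#' @param matrix Numeric matrix, probes x samples, log2 scale.
#' @param groups Per-sample labels in `{FTE, HGSOC}` (vector or factor,
#'   optionally named by sample).
#' @param name Dataset name.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, groups, name = "dataset") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix)) {
    stop("one group label per sample column required")
  }
  if (!all(groups %in% c("FTE", "HGSOC"))) {
    stop("group labels must be 'FTE' or 'HGSOC'")
  }
  keep <- stats::complete.cases(matrix) & apply(is.finite(matrix), 1L, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " probe row(s) with missing/non-finite values dropped")
    matrix <- matrix[keep, , drop = FALSE]
  }
  g <- factor(groups, levels = c("FTE", "HGSOC"))
  if (any(table(g) < 2L)) stop("need at least 2 samples per group")
  structure(list(matrix = matrix, groups = g, name = name,
                 n_dropped = n_dropped),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset '", x$name, "': ", nrow(x$matrix), " probes x ",
      ncol(x$matrix), " samples (FTE n=", sum(x$groups == "FTE"),
      ", HGSOC n=", sum(x$groups == "HGSOC"), ")\n", sep = "")
  if (x$n_dropped > 0L) cat(x$n_dropped, "probe row(s) dropped for missingness\n")
  invisible(x)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with columns probe_id, gene_symbol, chrom, gene_start, gene_end
#' (1-based inclusive). A gene symbol may map to several probes; probe ids
#' must be unique.
#'
#' @param path Path to the annotation TSV (with header).
#' @return A validated annotation data.frame.
#' @export
read_annotation_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_symbol", "chrom", "gene_start", "gene_end")
  if (!all(req %in% names(tab))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  }
  validate_annotation(tab[req])
}

validate_annotation <- function(annot) {
  if (anyDuplicated(annot$probe_id)) stop("duplicate probe_id in annotation")
  if (any(annot$gene_start > annot$gene_end)) {
    stop("annotation has gene_start > gene_end")
  }
  if (any(annot$gene_start < 1)) stop("annotation has gene_start < 1")
  rownames(annot) <- NULL
  annot
}

#' Read a gene x tissue expression table
#'
#' TSV with gene symbols in the first column and tissue names in the
#' header; values are nonnegative resource-native expression units
#' (TPM-like). Ranking downstream is within-resource, so units need not
#' match between resources.
#'
#' @param path Path to the TSV.
#' @param resource Resource name (e.g. `"GTEx-like"`).
#' @return A numeric matrix, genes x tissues, with a `resource` attribute.
#' @export
read_tissue_tsv <- function(path, resource = basename(path)) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("non-numeric cell(s) in tissue table ", path)
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression value in ", path)
  if (anyDuplicated(colnames(mat))) stop("duplicate tissue names in ", path)
  attr(mat, "resource") <- resource
  mat
}

#' Read an LD proxy table
#'
#' TSV with header columns index_rsid, proxy_rsid, chrom, pos (1-based),
#' r2. Used only to verify that proxies of the index risk SNPs fall inside
#' the merged blocks; r-squared is consumed, never computed.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame.
#' @export
read_ld_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("index_rsid", "proxy_rsid", "chrom", "pos", "r2")
  if (!all(req %in% names(tab))) {
    stop("LD table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(tab$r2 < 0 | tab$r2 > 1)) stop("r2 outside [0, 1]")
  tab[req]
}

#' Read reviewer localization labels
#'
#' TSV with header columns gene_symbol, reviewer_a, reviewer_b and an
#' optional adjudication column (empty/NA where no joint decision exists).
#' Labels may be enum codes (see [localization_classes()]) or the
#' free-text vocabulary used in published tables (mapped via
#' [map_localization_label()]).
#'
#' @param path Path to the TSV.
#' @return A list with data.frames `a`, `b` (gene_symbol, class) and
#'   `adjudications` (possibly zero rows).
#' @export
read_reviewer_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("gene_symbol", "reviewer_a", "reviewer_b")
  if (!all(req %in% names(tab))) {
    stop("reviewer table must have columns: ", paste(req, collapse = ", "))
  }
  adj <- if ("adjudication" %in% names(tab)) tab$adjudication else
    rep(NA_character_, nrow(tab))
  list(
    a = data.frame(gene_symbol = tab$gene_symbol,
                   class = map_localization_label(tab$reviewer_a),
                   stringsAsFactors = FALSE),
    b = data.frame(gene_symbol = tab$gene_symbol,
                   class = map_localization_label(tab$reviewer_b),
                   stringsAsFactors = FALSE),
    adjudications = data.frame(
      gene_symbol = tab$gene_symbol[!is.na(adj)],
      class = map_localization_label(adj[!is.na(adj)]),
      stringsAsFactors = FALSE)
  )
}

#' Read the packaged candidate-gene summary table
#'
#' Reads a TSV with columns block_label, block_coords, gene_symbol,
#' hpa_validation, localization, subcellular, mapping the published
#' localization vocabulary onto the internal class enum. The packaged
#' fixture (`system.file("extdata", "table1.tsv", package = "cilioprior")`)
#' holds the 28 shortlisted candidate genes with their consensus
#' immunohistochemistry localization.
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A data.frame with an added `class` column of localization enum
#'   codes.
#' @export
read_table1 <- function(path = system.file("extdata", "table1.tsv",
                                           package = "cilioprior")) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  req <- c("block_label", "block_coords", "gene_symbol", "hpa_validation",
           "localization", "subcellular")
  if (!all(req %in% names(tab))) {
    stop("candidate table must have columns: ", paste(req, collapse = ", "))
  }
  legal_val <- c("Enhanced", "Approved", "Supported", "Uncertain", "NA")
  if (!all(tab$hpa_validation %in% legal_val)) {
    stop("illegal hpa_validation value")
  }
  tab$class <- map_localization_label(tab$localization)
  tab
}

#' Map published localization vocabulary to the internal enum
#'
#' `"Ciliated cells"` becomes `ciliated`, `"Ciliated cells (not all)"`
#' becomes `ciliated_subset`, `"Serous"` becomes `serous`,
#' `"Serous and ciliated cells"` becomes `ciliated_and_serous`,
#' `"Not detected"` becomes `not_expressed`, `"Not available"` becomes
#' `not_available`, `"Ambiguous"` becomes `ambiguous`. Strings already in
#' enum form pass through unchanged.
#'
#' @param x Character vector of labels.
#' @return Character vector of enum codes.
#' @export
map_localization_label <- function(x) {
  vocab <- c(
    "Ciliated cells" = "ciliated",
    "Ciliated cells (not all)" = "ciliated_subset",
    "Serous" = "serous",
    "Serous cells" = "serous",
    "Serous and ciliated cells" = "ciliated_and_serous",
    "Ciliated and serous cells" = "ciliated_and_serous",
    "Not detected" = "not_expressed",
    "Not expressed" = "not_expressed",
    "Not available" = "not_available",
    "Ambiguous" = "ambiguous"
  )
  out <- ifelse(x %in% localization_classes(), x,
                unname(vocab[x]))
  if (any(is.na(out) & !is.na(x))) {
    stop("unmappable localization label(s): ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  }
  out
}
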