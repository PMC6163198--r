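# Two-reviewer immunohistochemistry localization consensus and the
# block-level summary statistics.

#' Legal localization classes
#'
#' The consensus enum: `ciliated`, `ciliated_subset` (positivity in only
#' some ciliated cells), `serous`, `ciliated_and_serous`, `not_expressed`,
#' `ambiguous`, `not_available`. The derived "ciliated-positive" predicate
#' covers `ciliated`, `ciliated_subset` and `ciliated_and_serous`.
#'
#' @return Character vector of the seven class codes.
#' @export
localization_classes <- function() {
  c("ciliated", "ciliated_subset", "serous", "ciliated_and_serous",
    "not_expressed", "ambiguous", "not_available")
}

#' Ciliated-positive predicate
#'
#' @param class Character vector of localization class codes.
#' @return Logical vector: consensus localization includes ciliated cells.
#' @export
is_ciliated_positive <- function(class) {
  class %in% c("ciliated", "ciliated_subset", "ciliated_and_serous")
}

#' Merge two reviewers' localization calls
#'
#' Agreement yields that class unadjudicated. Disagreement resolved by an
#' adjudication row yields the adjudicated class. Disagreement without an
#' adjudication falls back to `ambiguous` and is flagged unresolved.
#'
#' @param labels_a,labels_b Data.frames with columns `gene_symbol`,
#'   `class` (same gene set in both; order free).
#' @param adjudications Optional data.frame with the same columns, holding
#'   joint decisions for discordant genes.
#' @return Data.frame with columns `gene_symbol`, `class`, `adjudicated`,
#'   `unresolved`, sorted by gene symbol.
#' @examples
#' a <- data.frame(gene_symbol = "SPAG6", class = "ciliated")
#' b <- data.frame(gene_symbol = "SPAG6", class = "serous")
#' consensus_merge(a, b, data.frame(gene_symbol = "SPAG6", class = "ciliated"))
#' @export
consensus_merge <- function(labels_a, labels_b, adjudications = NULL) {
  stopifnot(is.data.frame(labels_a), is.data.frame(labels_b))
  check_classes <- function(df, who) {
    if (!all(df$class %in% localization_classes())) {
      stop("illegal localization class in ", who)
    }
    if (anyDuplicated(df$gene_symbol)) stop("duplicate gene in ", who)
  }
  check_classes(labels_a, "reviewer A labels")
  check_classes(labels_b, "reviewer B labels")
  only_a <- setdiff(labels_a$gene_symbol, labels_b$gene_symbol)
  only_b <- setdiff(labels_b$gene_symbol, labels_a$gene_symbol)
  if (length(only_a) + length(only_b) > 0L) {
    stop("gene set mismatch between reviewers: ",
         paste(c(only_a, only_b), collapse = ", "))
  }
  genes <- sort(labels_a$gene_symbol)
  ca <- labels_a$class[match(genes, labels_a$gene_symbol)]
  cb <- labels_b$class[match(genes, labels_b$gene_symbol)]
  adj <- rep(NA_character_, length(genes))
  if (!is.null(adjudications) && nrow(adjudications) > 0L) {
    check_classes(adjudications, "adjudications")
    adj[match(adjudications$gene_symbol, genes)] <- adjudications$class
  }
  agree <- ca == cb
  class <- ifelse(agree, ca, ifelse(is.na(adj), "ambiguous", adj))
  data.frame(
    gene_symbol = genes,
    class = class,
    adjudicated = !agree & !is.na(adj),
    unresolved = !agree & is.na(adj),
    stringsAsFactors = FALSE
  )
}

#' Summarize consensus localization over genes and blocks
#'
#' Computes the headline counts: ambiguous, not-available and
#' not-detected genes; "definite" genes (any other class); genes with a
#' ciliated-positive consensus; the number of distinct blocks holding at
#' least one ciliated-positive gene; and that number as a whole percent of
#' `total_blocks`, truncated toward zero (floor).
#'
#' @param records Data.frame with columns `gene_symbol`, `class` and
#'   (for the block statistics) `block_label`; records without a block
#'   label are excluded from the block counts with a warning.
#' @param total_blocks Total number of candidate blocks (denominator of
#'   the percentage).
#' @return A list of class `localization_summary` with fields
#'   `n_genes`, `n_ambiguous`, `n_not_available`, `n_not_detected`,
#'   `n_definite`, `n_ciliated_positive`, `n_distinct_blocks_ciliated`,
#'   `pct_blocks_ciliated`, `total_blocks`.
#' @export
summarize_localization <- function(records, total_blocks) {
  stopifnot(is.data.frame(records), length(total_blocks) == 1L)
  if (total_blocks <= 0) stop("total_blocks must be positive")
  if (!all(records$class %in% localization_classes())) {
    stop("illegal localization class in records")
  }
  cl <- records$class
  indefinite <- c("ambiguous", "not_available", "not_expressed")
  cilpos <- is_ciliated_positive(cl)
  if (!"block_label" %in% names(records)) {
    records$block_label <- rep(NA_character_, nrow(records))
  }
  no_block <- cilpos & is.na(records$block_label)
  if (any(no_block)) {
    warning(sum(no_block), " ciliated-positive record(s) without a block ",
            "label excluded from block statistics")
  }
  blocks_cil <- unique(records$block_label[cilpos &
                                             !is.na(records$block_label)])
  out <- list(
    n_genes = nrow(records),
    n_ambiguous = sum(cl == "ambiguous"),
    n_not_available = sum(cl == "not_available"),
    n_not_detected = sum(cl == "not_expressed"),
    n_definite = sum(!cl %in% indefinite),
    n_ciliated_positive = sum(cilpos),
    n_distinct_blocks_ciliated = length(blocks_cil),
    pct_blocks_ciliated = floor(100 * length(blocks_cil) / total_blocks),
    total_blocks = total_blocks
  )
  class(out) <- "localization_summary"
  out
}

#' @export
print.localization_summary <- function(x, ...) {
  cat("Localization consensus over", x$n_genes, "gene(s):\n")
  cat("  ambiguous:", x$n_ambiguous,
      "| not available:", x$n_not_available,
      "| not detected:", x$n_not_detected, "\n")
  cat("  definite:", x$n_definite,
      "of which ciliated-positive:", x$n_ciliated_positive, "\n")
  cat("  blocks with a ciliated-positive gene:",
      x$n_distinct_blocks_ciliated, "/", x$total_blocks,
      paste0("(", x$pct_blocks_ciliated, "%)"), "\n")
  invisible(x)
}
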