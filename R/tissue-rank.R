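# Tissue-specificity rank filter: keep genes for which a female
# genital-tract tissue occupies a top-k expression rank in both of two
# independent tissue-expression resources.

#' Rank-filter configuration
#'
#' @param shared_tissues Character vector of tissue names present in both
#'   resources (the study used 25).
#' @param target_tissues Female genital-tract tissues; must be a subset of
#'   `shared_tissues`.
#' @param k Rank cutoff: a target tissue must occupy one of the top `k`
#'   positions (the study used 2, "first or second position").
#' @return A list of class `rank_config`.
#' @export
rank_config <- function(shared_tissues,
                        target_tissues = c("cervix", "endometrium",
                                           "fallopian tube", "ovary"),
                        k = 2L) {
  stopifnot(is.character(shared_tissues), length(shared_tissues) >= 1L,
            k >= 1L, k <= length(shared_tissues))
  if (!all(target_tissues %in% shared_tissues)) {
    stop("target tissue(s) not in shared_tissues: ",
         paste(setdiff(target_tissues, shared_tissues), collapse = ", "))
  }
  structure(list(shared_tissues = shared_tissues,
                 target_tissues = target_tissues, k = as.integer(k)),
            class = "rank_config")
}

#' Restrict two tissue tables to the shared tissue panel
#'
#' Both tables are restricted to `cfg$shared_tissues` and column-ordered
#' identically. A tissue named in the config but absent from either table
#' is an error (the filter is undefined without its target tissues).
#'
#' @param tab_a,tab_b Gene x tissue matrices (see [read_tissue_tsv()]).
#' @param cfg A [rank_config()].
#' @return List with elements `a` and `b`, both restricted.
#' @export
align_tissues <- function(tab_a, tab_b, cfg) {
  stopifnot(inherits(cfg, "rank_config"))
  for (nm in list(list("A", tab_a), list("B", tab_b))) {
    miss <- setdiff(cfg$shared_tissues, colnames(nm[[2L]]))
    if (length(miss) > 0L) {
      stop("tissue(s) missing from resource ", nm[[1L]], ": ",
           paste(miss, collapse = ", "))
    }
  }
  list(a = tab_a[, cfg$shared_tissues, drop = FALSE],
       b = tab_b[, cfg$shared_tissues, drop = FALSE])
}

# Does some target tissue occupy a top-k position in this row?
# A target is in position <= k iff fewer than k NON-target tissues have
# strictly greater expression; ties therefore never demote a target.
target_in_top_k <- function(row, cfg) {
  if (all(row == 0)) return(structure(FALSE, note = "unexpressed"))
  nt <- row[setdiff(names(row), cfg$target_tissues)]
  any(vapply(cfg$target_tissues,
             function(t) sum(nt > row[[t]]) < cfg$k, logical(1L)))
}

#' Test one gene for genital-tract tissue specificity
#'
#' TRUE iff, in each resource independently, at least one target tissue
#' occupies a top-k rank (fewer than k non-target tissues strictly greater;
#' exact ties favor inclusion). An all-zero row in either resource fails
#' with an "unexpressed" note.
#'
#' @param row_a,row_b Named numeric vectors (one gene's expression over
#'   `cfg$shared_tissues`) from the two resources.
#' @param cfg A [rank_config()].
#' @return Logical scalar.
#' @export
passes_specificity <- function(row_a, row_b, cfg) {
  stopifnot(inherits(cfg, "rank_config"))
  row_a <- row_a[cfg$shared_tissues]
  row_b <- row_b[cfg$shared_tissues]
  isTRUE(as.logical(target_in_top_k(row_a, cfg))) &&
    isTRUE(as.logical(target_in_top_k(row_b, cfg)))
}

#' Filter candidate genes by two-resource tissue specificity
#'
#' Candidates absent from either resource are logged and dropped; the
#' rest are kept iff [passes_specificity()] holds. The attached `report`
#' attribute records, per evaluated gene, the best (smallest) target-tissue
#' rank in each resource, where rank = 1 + number of non-target tissues
#' strictly greater than the best target.
#'
#' @param genes Character vector of candidate gene symbols.
#' @param tab_a,tab_b Gene x tissue matrices.
#' @param cfg A [rank_config()].
#' @return Character vector of passing genes, with attributes `report`
#'   (data.frame) and `dropped` (genes absent from a resource).
#' @export
specificity_filter <- function(genes, tab_a, tab_b, cfg) {
  stopifnot(inherits(cfg, "rank_config"))
  al <- align_tissues(tab_a, tab_b, cfg)
  genes <- unique(genes)
  present <- genes[genes %in% rownames(al$a) & genes %in% rownames(al$b)]
  dropped <- setdiff(genes, present)
  if (length(dropped) > 0L) {
    message(length(dropped), " candidate gene(s) absent from a tissue ",
            "resource, dropped")
  }
  best_rank <- function(row) {
    nt <- row[setdiff(names(row), cfg$target_tissues)]
    1L + min(vapply(cfg$target_tissues,
                    function(t) sum(nt > row[[t]]), integer(1L)))
  }
  pass <- logical(length(present))
  ra <- rb <- integer(length(present))
  for (i in seq_along(present)) {
    row_a <- al$a[present[i], ]
    row_b <- al$b[present[i], ]
    pass[i] <- passes_specificity(row_a, row_b, cfg)
    ra[i] <- best_rank(row_a)
    rb[i] <- best_rank(row_b)
  }
  out <- present[pass]
  attr(out, "report") <- data.frame(
    gene_symbol = present, best_target_rank_a = ra, best_target_rank_b = rb,
    pass = pass, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}
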