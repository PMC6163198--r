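# Two-group differential expression: empirical-Bayes moderated t with
# variance shrinkage, BH adjustment, thresholding, and cross-dataset
# concordance.

#' Fit a moderated two-sample t-test across probes
#'
#' For each probe the log2 fold change is the HGSOC mean minus the FTE
#' mean. The pooled residual variance `s_g^2` (df `d_g = n1 + n2 - 2`) is
#' shrunk toward a prior: assuming `s_g^2 | sigma_g^2 ~ sigma_g^2
#' chisq(d_g)/d_g` and `1/sigma_g^2 ~ chisq(d0)/(d0 s0^2)`, the posterior
#' variance is `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the
#' moderated statistic `t = logFC / sqrt(s~^2 (1/n1 + 1/n2))` is referred
#' to a t distribution with `d0 + d_g` degrees of freedom. The prior
#' `(d0, s0^2)` is estimated by moment matching on `log s_g^2`: under the
#' hierarchical model `Var(log s_g^2) = trigamma(d_g/2) + trigamma(d0/2)`,
#' solved for `d0` by Newton inversion of the trigamma function. When the
#' observed log-variances are underdispersed relative to `chisq(d_g)`
#' alone, `d0` diverges and full shrinkage (`s~^2 = s0^2`, normal
#' reference) is used.
#'
#' Probes with zero residual variance are excluded from testing and listed
#' in the `excluded` element of the result.
#'
#' @param ds An [expression_dataset()].
#' @param method `"moderated"` (default) for empirical-Bayes shrinkage;
#'   `"plain"` for the unshrunk pooled-variance t (`d0 = 0`); `"welch"`
#'   for Welch's unequal-variance t.
#' @return An object of class `modt_fit`: list with `model` (d0, s0_sq,
#'   d_g, method), `table` (data.frame: probe_id, logFC, t, df, p,
#'   s_g_sq, s_tilde_sq), `excluded`, `n1`, `n2`, `name`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200, 7), 10, 20,
#'             dimnames = list(paste0("p", 1:10), paste0("s", 1:20)))
#' ds <- expression_dataset(m, rep(c("FTE", "HGSOC"), each = 10))
#' fit <- fit_moderated_t(ds)
#' summary(fit)
#' @export
fit_moderated_t <- function(ds, method = c("moderated", "plain", "welch")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  m <- ds$matrix
  g1 <- ds$groups == "FTE"
  g2 <- ds$groups == "HGSOC"
  n1 <- sum(g1); n2 <- sum(g2)
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, g2, drop = FALSE])
  logfc <- mean2 - mean1
  v1 <- apply(m[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(m[, g2, drop = FALSE], 1L, stats::var)
  d_g <- n1 + n2 - 2L
  s_g_sq <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_g

  excluded <- rownames(m)[s_g_sq <= 0]
  keep <- s_g_sq > 0
  if (length(excluded) > 0L) {
    message(length(excluded), " zero-variance probe(s) excluded from testing")
  }
  logfc <- logfc[keep]; s_g_sq <- s_g_sq[keep]
  v1 <- v1[keep]; v2 <- v2[keep]
  probe_id <- rownames(m)[keep]

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- logfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    model <- list(d0 = NA_real_, s0_sq = NA_real_, d_g = d_g,
                  method = "welch")
    s_tilde_sq <- s_g_sq
  } else if (method == "plain") {
    s_tilde_sq <- s_g_sq
    tstat <- logfc / sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
    df <- rep(d_g, length(logfc))
    model <- list(d0 = 0, s0_sq = NA_real_, d_g = d_g, method = "plain")
  } else {
    if (length(s_g_sq) < 2L) {
      stop("fewer than 2 testable probes: the variance prior cannot be ",
           "estimated; use method = 'plain'")
    }
    prior <- fit_variance_prior(s_g_sq, d_g)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    if (is.infinite(d0)) {
      s_tilde_sq <- rep(s0_sq, length(s_g_sq))
      df <- rep(Inf, length(s_g_sq))
    } else {
      s_tilde_sq <- (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
      df <- rep(d0 + d_g, length(s_g_sq))
    }
    tstat <- logfc / sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
    model <- list(d0 = d0, s0_sq = s0_sq, d_g = d_g, method = "moderated")
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(
    model = model,
    table = data.frame(probe_id = probe_id, logFC = unname(logfc),
                       t = unname(tstat), df = unname(df), p = unname(p),
                       s_g_sq = unname(s_g_sq),
                       s_tilde_sq = unname(s_tilde_sq),
                       stringsAsFactors = FALSE),
    excluded = excluded, n1 = n1, n2 = n2, name = ds$name
  ), class = "modt_fit")
}

# Moment matching of the inverse-chi-square variance prior on log s^2.
# Var(log s_g^2) = trigamma(d_g/2) + trigamma(d0/2); solve for d0, then
# back out s0^2 from the mean.
fit_variance_prior <- function(s_g_sq, d_g) {
  z <- log(s_g_sq)
  zbar <- mean(z)
  excess <- stats::var(z) - trigamma(d_g / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(zbar - digamma(d_g / 2) + log(d_g / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(zbar - digamma(d_g / 2) + log(d_g / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(x) = y for x > 0.
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' @export
print.modt_fit <- function(x, ...) {
  cat("Moderated t fit ('", x$name, "', method = ", x$model$method, ")\n",
      sep = "")
  cat("  probes tested:", nrow(x$table),
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " excluded, zero variance)") else "",
      "\n")
  cat("  groups: FTE n =", x$n1, ", HGSOC n =", x$n2,
      "; residual df =", x$model$d_g, "\n")
  if (x$model$method == "moderated") {
    cat("  variance prior: d0 =", format(x$model$d0, digits = 4),
        ", s0^2 =", format(x$model$s0_sq, digits = 4), "\n")
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.modt_fit <- function(object, alpha = 0.05, ...) {
  res <- de_results(object)
  print(object)
  cat("  probes with q <", alpha, ":", sum(res$q < alpha), "\n")
  cat("  logFC range:", paste(format(range(res$logFC), digits = 3),
                              collapse = " .. "), "\n")
  invisible(res)
}

#' @exportS3Method stats::coef
coef.modt_fit <- function(object, ...) {
  stats::setNames(object$table$logFC, object$table$probe_id)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with enforced monotonicity and
#' capping at 1; output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (q-values), same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression result table
#'
#' Augments the per-probe table of a [fit_moderated_t()] fit with
#' BH-adjusted p-values.
#'
#' @param fit A `modt_fit`.
#' @return Data.frame with columns probe_id, logFC, t, df, p, q.
#' @export
de_results <- function(fit) {
  stopifnot(inherits(fit, "modt_fit"))
  out <- fit$table[c("probe_id", "logFC", "t", "df", "p")]
  out$q <- bh_adjust(out$p)
  out
}

#' Significance thresholds for the differential-expression filter
#'
#' Defaults are the study's published cutoffs: adjusted p strictly below
#' 0.05 and |logFC| strictly above 1 (log2 units).
#'
#' @param alpha_q Adjusted-p cutoff (strict `<`).
#' @param min_abs_logfc Absolute log2-fold-change cutoff (strict `>`).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(alpha_q = 0.05, min_abs_logfc = 1.0) {
  stopifnot(alpha_q > 0, alpha_q < 1, min_abs_logfc >= 0)
  structure(list(alpha_q = alpha_q, min_abs_logfc = min_abs_logfc),
            class = "de_thresholds")
}

#' Retain significant probes
#'
#' A probe is retained iff `q < alpha_q` and `|logFC| > min_abs_logfc`
#' (both strict). The direction of change (+1 up in HGSOC, -1 down) is
#' attached.
#'
#' @param res A result table from [de_results()].
#' @param th A [de_thresholds()].
#' @return Subset of `res` with an added `direction` column.
#' @export
apply_thresholds <- function(res, th = de_thresholds()) {
  stopifnot(inherits(th, "de_thresholds"), "q" %in% names(res))
  keep <- res$q < th$alpha_q & abs(res$logFC) > th$min_abs_logfc
  out <- res[keep, , drop = FALSE]
  out$direction <- sign(out$logFC)
  rownames(out) <- NULL
  out
}

#' Concordant probes between two datasets
#'
#' Probes significant in both datasets with the same direction of change.
#' A sign flip between datasets never counts as concordance.
#'
#' @param set_a,set_b Significant sets from [apply_thresholds()] on the
#'   two datasets.
#' @return Data.frame with probe_id, direction and per-dataset logFC and q
#'   (suffixes `_a`, `_b`).
#' @export
concordant_probes <- function(set_a, set_b) {
  stopifnot(all(c("probe_id", "direction") %in% names(set_a)),
            all(c("probe_id", "direction") %in% names(set_b)))
  m <- merge(set_a[c("probe_id", "direction", "logFC", "q")],
             set_b[c("probe_id", "direction", "logFC", "q")],
             by = "probe_id", suffixes = c("_a", "_b"))
  m <- m[m$direction_a == m$direction_b, , drop = FALSE]
  out <- data.frame(probe_id = m$probe_id, direction = m$direction_a,
                    logFC_a = m$logFC_a, logFC_b = m$logFC_b,
                    q_a = m$q_a, q_b = m$q_b, stringsAsFactors = FALSE)
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
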