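# Brute-force oracles, kept independent of the package implementation.

# BH step-up from the definition: q_(i) = min_{j >= i} m * p_(j) / j,
# computed literally with nested scans.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(cands))
  }
  q
}

# Single-linkage block partition as the transitive closure of the
# all-pairs relation |pos_i - pos_j| < threshold on the same chromosome.
oracle_partition <- function(snps, threshold) {
  n <- nrow(snps)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (snps$chrom[i] == snps$chrom[j] &&
          abs(snps$pos[i] - snps$pos[j]) < threshold &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(snps$rsid, comp)
}

# All-pairs overlap scan: 1-based inclusive intervals overlap iff
# start_a <= end_b and end_a >= start_b on the same chromosome.
oracle_overlap <- function(genes, blocks) {
  hits <- NULL
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(blocks))) {
    if (genes$chrom[i] == blocks$chrom[j] &&
        genes$gene_start[i] <= blocks$end[j] &&
        genes$gene_end[i] >= blocks$start[j]) {
      hits <- rbind(hits, data.frame(probe_id = genes$probe_id[i],
                                     block_label = blocks$label[j]))
    }
  }
  hits
}

# Sort-and-inspect rank decision with the same tie rule: a target is in
# position <= k iff fewer than k non-target tissues are strictly greater.
oracle_top_k <- function(row, targets, k) {
  if (all(row == 0)) return(FALSE)
  ok <- FALSE
  for (t in targets) {
    greater <- 0
    for (s in setdiff(names(row), targets)) {
      if (row[[s]] > row[[t]]) greater <- greater + 1
    }
    if (greater < k) ok <- TRUE
  }
  ok
}

# Tiny reusable fixtures -----------------------------------------------

random_snp_table <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             span = 2e7) {
  # positions start past the default flank so no block needs clamping
  data.frame(rsid = sprintf("rs%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(span, n) + 1e6,
             stringsAsFactors = FALSE)
}

make_dataset <- function(n_probes, n1, n2, delta = NULL, d0 = 4,
                         s0_sq = 0.05, name = "sim") {
  if (is.null(delta)) delta <- rep(0, n_probes)
  sigma2 <- s0_sq * d0 / rchisq(n_probes, df = d0)
  mu <- rnorm(n_probes, 7, 1)
  ns <- n1 + n2
  m <- matrix(rnorm(n_probes * ns, mean = mu, sd = sqrt(sigma2)),
              n_probes, ns)
  m[, (n1 + 1):ns] <- m[, (n1 + 1):ns] + delta
  dimnames(m) <- list(sprintf("p%05d", seq_len(n_probes)),
                      paste0("s", seq_len(ns)))
  expression_dataset(m, rep(c("FTE", "HGSOC"), c(n1, n2)), name = name)
}
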