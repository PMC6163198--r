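test_that("plain mode reproduces the pooled-variance two-sample t exactly", {
  set.seed(11)
  ds <- make_dataset(50, 6, 8)
  fit <- fit_moderated_t(ds, method = "plain")
  m <- ds$matrix
  g1 <- ds$groups == "FTE"; g2 <- !g1
  for (i in c(1, 17, 50)) {
    n1 <- sum(g1); n2 <- sum(g2)
    sp2 <- ((n1 - 1) * var(m[i, g1]) + (n2 - 1) * var(m[i, g2])) /
      (n1 + n2 - 2)
    t_ref <- (mean(m[i, g2]) - mean(m[i, g1])) /
      sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(fit$table$t[i], t_ref)
    expect_equal(fit$table$df[i], n1 + n2 - 2)
  }
})

test_that("underdispersed variances trigger full shrinkage to the prior", {
  set.seed(12)
  n <- 200
  mu <- rnorm(n, 7)
  # constant true variance: log s^2 spread is below trigamma(d_g/2)
  m <- matrix(rnorm(n * 20, mu, sd = sqrt(0.05)), n, 20,
              dimnames = list(sprintf("p%03d", 1:n), NULL))
  ds <- expression_dataset(m, rep(c("FTE", "HGSOC"), each = 10))
  fit <- fit_moderated_t(ds)
  expect_true(is.infinite(fit$model$d0))
  expect_true(all(fit$table$s_tilde_sq == fit$model$s0_sq))
  expect_true(all(is.infinite(fit$table$df)))
})

test_that("null simulation is calibrated and the prior is recovered", {
  set.seed(2024)
  n <- 2000
  ds <- make_dataset(n, 10, 10, d0 = 4, s0_sq = 0.05)
  fit <- fit_moderated_t(ds)
  # moment-matched prior within 25% relative error of the truth
  expect_lt(abs(fit$model$d0 - 4) / 4, 0.25)
  expect_lt(abs(fit$model$s0_sq - 0.05) / 0.05, 0.25)
  # type-I error 0.05 within 3 Monte-Carlo standard errors
  frac <- mean(fit$table$p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * mc_se)
})

test_that("moderated fit matches the reference empirical-Bayes toolchain", {
  skip_if_not_installed("limma")
  set.seed(33)
  ds <- make_dataset(400, 10, 10)
  fit <- fit_moderated_t(ds)
  design <- model.matrix(~ ds$groups)
  lf <- limma::eBayes(limma::lmFit(ds$matrix, design))
  expect_equal(fit$model$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$model$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$logFC, unname(lf$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$table$t, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("statistics are antisymmetric under group-label swap", {
  set.seed(21)
  ds <- make_dataset(100, 5, 7)
  swapped <- expression_dataset(
    ds$matrix,
    ifelse(as.character(ds$groups) == "FTE", "HGSOC", "FTE"),
    name = "swapped")
  f1 <- fit_moderated_t(ds)
  f2 <- fit_moderated_t(swapped)
  expect_equal(f1$table$logFC, -f2$table$logFC)
  expect_equal(f1$table$t, -f2$table$t)
  expect_equal(f1$table$p, f2$table$p)
})

test_that("zero-variance probes are excluded with a message", {
  set.seed(5)
  m <- matrix(rnorm(200, 7), 20, 10)
  m[3, ] <- 5  # constant row
  dimnames(m) <- list(sprintf("p%02d", 1:20), paste0("s", 1:10))
  ds <- expression_dataset(m, rep(c("FTE", "HGSOC"), each = 5))
  expect_message(fit <- fit_moderated_t(ds), "zero-variance")
  expect_equal(fit$excluded, "p03")
  expect_equal(nrow(fit$table), 19L)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (rep in 1:10) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # monotone nondecreasing when sorted by p
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("thresholds are strict on both q and logFC", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    logFC = c(1.01, 2, 1.0, -1.5),
                    t = 0, df = 18, p = 0,
                    q = c(0.049, 0.05, 0.01, 0.02))
  kept <- apply_thresholds(res, de_thresholds())
  expect_equal(kept$probe_id, c("a", "d"))
  expect_equal(kept$direction, c(1, -1))
})

test_that("concordance requires joint significance with matching sign", {
  a <- data.frame(probe_id = c("p1", "p2", "p3"), direction = c(1, 1, -1),
                  logFC = c(2, 1.5, -2), q = c(0.01, 0.02, 0.03))
  b <- data.frame(probe_id = c("p1", "p2", "p4"), direction = c(1, -1, 1),
                  logFC = c(1.8, -1.2, 2), q = c(0.02, 0.01, 0.01))
  cc <- concordant_probes(a, b)
  expect_equal(cc$probe_id, "p1")   # p2 flips sign, p3/p4 unmatched
  expect_equal(cc$logFC_a, 2)
  expect_equal(cc$logFC_b, 1.8)
})

test_that("retention is monotone in the planted effect size and recovery is calibrated", {
  th <- de_thresholds()
  retained <- sapply(c(0.5, 1.5, 3), function(effect) {
    set.seed(77)  # same noise realisation for every effect size
    n <- 600
    de <- rep(c(TRUE, FALSE), c(30, n - 30))
    delta <- ifelse(de, effect, 0) * rep(c(1, -1), length.out = n)
    ds <- make_dataset(n, 10, 10, delta = delta)
    res <- de_results(fit_moderated_t(ds))
    sig <- apply_thresholds(res, th)
    sum(sig$probe_id %in% rownames(ds$matrix)[de])
  })
  expect_true(all(diff(retained) >= 0))
  # planted logFC +/- 2 in 5% of probes: sensitivity >= 0.9, FDR <= 0.10
  set.seed(88)
  n <- 2000
  de <- seq_len(n) %in% sample(n, 0.05 * n)
  delta <- ifelse(de, 2, 0) * rep(c(1, -1), length.out = n)
  ds <- make_dataset(n, 10, 10, delta = delta)
  sig <- apply_thresholds(de_results(fit_moderated_t(ds)), th)
  truth <- rownames(ds$matrix)[de]
  expect_gte(sum(sig$probe_id %in% truth) / length(truth), 0.9)
  expect_lte(mean(!sig$probe_id %in% truth), 0.10)
})
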