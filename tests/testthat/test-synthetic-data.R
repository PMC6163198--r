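test_that("planted SNP clusters are recovered exactly as blocks", {
  cfg <- sim_config(seed = 3,
                    cluster_sizes = c(2L, 1L, 3L, 1L, 1L),
                    chroms = c("chr1", "chr2", "chr3"))
  panel <- gen_snp_panel(cfg)
  expect_equal(nrow(panel$snps), 8L)
  blocks <- build_blocks(panel$snps,
                         interval_config(cfg$flank, cfg$merge_threshold))
  expect_equal(nrow(blocks), 5L)
  # recovered member lists equal the planted partition
  got <- sort(vapply(blocks$member_snps,
                     function(g) paste(sort(g), collapse = ","), ""))
  want <- sort(vapply(split(panel$truth$rsid, panel$truth$cluster),
                      function(g) paste(sort(g), collapse = ","), ""))
  expect_equal(got, unname(want))

  single <- gen_snp_panel(sim_config(seed = 3, cluster_sizes = 1L,
                                     n_indels = 0L))
  expect_equal(nrow(single$snps), 1L)
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_probes = 60L, frac_de = 0.1,
                    cluster_sizes = c(1L, 2L, 1L), n_indels = 1L,
                    n_target_specific = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the SNP panel
  d3 <- withr::local_tempdir()
  simulate_inputs(sim_config(seed = 10, n_probes = 60L, frac_de = 0.1,
                             cluster_sizes = c(1L, 2L, 1L), n_indels = 1L,
                             n_target_specific = 3L), d3)
  expect_false(identical(readLines(file.path(d1, "snps.bed")),
                         readLines(file.path(d3, "snps.bed"))))
})

test_that("null expression generation keeps the retained fraction near FDR control", {
  cfg <- sim_config(seed = 14, n_probes = 1500L, frac_de = 0)
  expr <- gen_expression_pair(cfg)
  sig_a <- apply_thresholds(de_results(fit_moderated_t(expr$ds_a)))
  # with no planted signal, BH at 0.05 plus the |logFC| > 1 filter keeps
  # (essentially) nothing
  expect_lte(nrow(sig_a), ceiling(0.001 * cfg$n_probes))
})

test_that("planted DE genes are recovered with high power", {
  cfg <- sim_config(seed = 15, n_probes = 1200L, frac_de = 0.05,
                    logfc_effect = 3)
  expr <- gen_expression_pair(cfg)
  sig <- apply_thresholds(de_results(fit_moderated_t(expr$ds_a)))
  truth <- expr$truth$probe_id[expr$truth$de]
  expect_gte(mean(truth %in% sig$probe_id), 0.9)
  # planted signs agree with the fitted direction for recovered probes
  rec <- sig[sig$probe_id %in% truth, ]
  planted_sign <- expr$truth$sign[match(rec$probe_id, expr$truth$probe_id)]
  expect_equal(rec$direction, planted_sign)
})

test_that("gene placement respects the in-block fraction", {
  cfg <- sim_config(seed = 16, n_probes = 300L, frac_de = 0.1,
                    cluster_sizes = c(rep(1L, 6), 2L))
  panel <- gen_snp_panel(cfg)
  blocks <- build_blocks(panel$snps)
  expr <- gen_expression_pair(cfg, blocks)
  in_block <- function(g) any(blocks$chrom == g$chrom &
                                g$gene_start <= blocks$end &
                                g$gene_end >= blocks$start)
  genes <- unique(expr$annot$gene_symbol)
  de_genes <- unique(expr$truth$gene_symbol[expr$truth$de])
  for (g in genes) {
    row <- expr$annot[expr$annot$gene_symbol == g, ][1, ]
    expect_equal(in_block(row), g %in% de_genes, label = g)
  }
})

test_that("reviewer simulation: consensus always equals the truth", {
  genes <- sprintf("G%02d", 1:30)
  for (rate in c(0, 0.3, 1)) {
    cfg <- sim_config(seed = 21, discordance_rate = rate)
    truth <- gen_true_classes(cfg, genes)
    rev <- gen_reviewer_labels(cfg, truth)
    cons <- consensus_merge(rev$a, rev$b, rev$adjudications)
    expect_equal(cons$class[match(truth$gene_symbol, cons$gene_symbol)],
                 truth$class)
    if (rate == 0) expect_equal(sum(cons$adjudicated), 0L)
    if (rate == 1) expect_true(all(cons$adjudicated))
    expect_false(any(cons$unresolved))
  }
  # flagged count is reproducible under the same seed
  cfg <- sim_config(seed = 22, discordance_rate = 0.3)
  t1 <- gen_true_classes(cfg, genes)
  n_flagged <- replicate(2, sum(consensus_merge(
    gen_reviewer_labels(cfg, t1)$a,
    gen_reviewer_labels(cfg, t1)$b,
    gen_reviewer_labels(cfg, t1)$adjudications)$adjudicated))
  expect_equal(n_flagged[1], n_flagged[2])
})
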