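make_concordant <- function(probes, ...) {
  data.frame(probe_id = probes, direction = 1,
             logFC_a = 2, logFC_b = 2, q_a = 0.01, q_b = 0.01,
             stringsAsFactors = FALSE, ...)
}

test_that("gene spans are assigned to blocks by any-base overlap", {
  blocks <- data.frame(label = c("B1", "B2"),
                       chrom = c("chr20", "chr20"),
                       start = c(56330568, 60000000),
                       end = c(58330569, 62000000))
  annot <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbol = c("G1", "G2", "G3", "G4"),
    chrom = "chr20",
    gene_start = c(57000000, 56330000, 58330570, 59000000),
    gene_end = c(57010000, 56330568, 58340000, 59500000))
  cc <- make_concordant(c("p1", "p2", "p3", "p4"))
  hits <- assign_to_blocks(cc, annot, blocks)
  expect_setequal(hits$probe_id[hits$block_label == "B1"], c("p1", "p2"))
  # p2 touches the block start by exactly one base (boundary inclusive)
  # p3 starts one base past the block end; p4 falls between blocks
  expect_false("p3" %in% hits$probe_id)
  expect_false("p4" %in% hits$probe_id)
})

test_that("a gene overlapping two overlapping blocks yields two hits", {
  blocks <- data.frame(label = c("B1", "B2"), chrom = "chr19",
                       start = c(1e6, 2e6), end = c(3e6, 4e6))
  annot <- data.frame(probe_id = "p1", gene_symbol = "G1", chrom = "chr19",
                      gene_start = 2.4e6, gene_end = 2.5e6)
  hits <- assign_to_blocks(make_concordant("p1"), annot, blocks)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$block_label, c("B1", "B2"))
})

test_that("hit sets equal an all-pairs brute-force overlap scan", {
  set.seed(123)
  for (rep in 1:6) {
    n_g <- sample(5:25, 1); n_b <- sample(2:8, 1)
    annot <- data.frame(
      probe_id = sprintf("p%02d", seq_len(n_g)),
      gene_symbol = sprintf("G%02d", seq_len(n_g)),
      chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
      gene_start = sample.int(1e6, n_g))
    annot$gene_end <- annot$gene_start + sample.int(2e5, n_g)
    blocks <- data.frame(
      label = sprintf("B%02d", seq_len(n_b)),
      chrom = sample(c("chr1", "chr2"), n_b, replace = TRUE),
      start = sample.int(1e6, n_b))
    blocks$end <- blocks$start + sample.int(4e5, n_b)
    hits <- assign_to_blocks(make_concordant(annot$probe_id), annot, blocks)
    want <- oracle_overlap(annot, blocks)
    got_keys <- sort(paste(hits$probe_id, hits$block_label))
    want_keys <- if (is.null(want)) character(0) else
      sort(paste(want$probe_id, want$block_label))
    expect_equal(got_keys, want_keys)
    # post-hoc: every emitted hit genuinely overlaps its block
    for (i in seq_len(nrow(hits))) {
      b <- blocks[blocks$label == hits$block_label[i], ]
      expect_true(hits$chrom[i] == b$chrom &&
                    hits$gene_start[i] <= b$end &&
                    hits$gene_end[i] >= b$start)
    }
  }
})

test_that("output is invariant to probe and block ordering", {
  set.seed(5)
  annot <- data.frame(probe_id = sprintf("p%02d", 1:10),
                      gene_symbol = sprintf("G%02d", 1:10),
                      chrom = "chr1",
                      gene_start = sample.int(5e6, 10))
  annot$gene_end <- annot$gene_start + 1e4
  blocks <- data.frame(label = c("B1", "B2"), chrom = "chr1",
                       start = c(1, 2.5e6), end = c(2.6e6, 5.1e6))
  cc <- make_concordant(annot$probe_id)
  h1 <- assign_to_blocks(cc, annot, blocks)
  h2 <- assign_to_blocks(cc[sample(nrow(cc)), ],
                         annot[sample(nrow(annot)), ],
                         blocks[2:1, ])
  expect_equal(h1, h2, ignore_attr = TRUE)
})

test_that("unannotated probes are excluded with a warning", {
  annot <- data.frame(probe_id = "p1", gene_symbol = "G1", chrom = "chr1",
                      gene_start = 100, gene_end = 200)
  blocks <- data.frame(label = "B1", chrom = "chr1", start = 1, end = 1000)
  expect_warning(
    hits <- assign_to_blocks(make_concordant(c("p1", "p_unknown")),
                             annot, blocks),
    "without annotation")
  expect_equal(attr(hits, "excluded"), "p_unknown")
  expect_equal(hits$probe_id, "p1")
})

test_that("gene-level dedupe keeps the best probe per gene and block", {
  hits <- data.frame(
    probe_id = c("pB", "pA", "pC", "pD"),
    gene_symbol = c("G1", "G1", "G1", "G2"),
    block_label = c("B1", "B1", "B2", "B1"),
    chrom = "chr1", gene_start = 1, gene_end = 10,
    direction = 1,
    logFC_a = c(2, 3, 1.5, 1.2), logFC_b = 2,
    q_a = c(0.01, 0.01, 0.02, 0.03), q_b = 0.01)
  out <- dedupe_by_gene(hits)
  # G1/B1: tie on q_a broken by larger |logFC_a| -> pA; one row per block
  expect_equal(out$probe_id[out$gene_symbol == "G1" &
                              out$block_label == "B1"], "pA")
  expect_equal(nrow(out[out$gene_symbol == "G1", ]), 2L)
  expect_equal(nrow(out), 3L)
  expect_equal(nrow(dedupe_by_gene(hits[0, ])), 0L)
})
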