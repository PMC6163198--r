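Package: cilioprior
Title: Candidate-Gene Prioritization for Epithelial Ovarian Cancer Risk Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline that prioritizes candidate genes at
    epithelial ovarian cancer (EOC) genome-wide association risk loci.
    Risk SNPs are expanded into 2-Mb genomic blocks merged by a
    single-linkage distance rule, genes are filtered by concordant
    differential expression between fallopian tube epithelium and
    high-grade serous ovarian cancer in two independent datasets
    (empirical-Bayes moderated t-test with Benjamini-Hochberg false
    discovery rate control), intersected with the risk blocks, filtered by
    a two-resource female-genital-tract tissue-specificity rank criterion,
    and summarized by two-reviewer immunohistochemistry localization
    consensus. Includes a seeded synthetic-data generator with planted
    ground truth so the full funnel is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr
Config/testthat/edition: 3
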