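---
title: "Prioritizing candidate genes at ovarian cancer risk loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes at ovarian cancer risk loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilioprior)
```

## The problem

High-grade serous ovarian cancer (HGSOC) is thought to arise from the
fallopian tube epithelium (FTE), and genome-wide association studies
(GWAS) have mapped dozens of epithelial ovarian cancer (EOC) risk
variants. A risk SNP marks a genomic neighbourhood, not a gene.
`cilioprior` implements a transparent funnel that narrows the
neighbourhoods to genes with converging evidence:

1. **Locus intervals** — each risk SNP is flanked by 1 Mb on each side
   (a 2-Mb search window); SNPs less than 1 Mb apart are pooled into one
   interval.
2. **Differential expression** — candidate genes should differ between
   non-malignant FTE and HGSOC, concordantly in two independent
   expression datasets.
3. **Genomic intersection** — differentially expressed genes are kept
   only if their span overlaps a risk interval.
4. **Tissue specificity** — candidates must rank a female genital-tract
   tissue (cervix, endometrium, fallopian tube, ovary) in the top two
   positions of two independent tissue-expression resources.
5. **Protein localization** — two reviewers independently classify
   immunohistochemistry staining; their consensus flags genes expressed
   in the ciliated cells of the FTE.

Every stage is an exported function; `run_pipeline()` chains them and
writes a machine-readable funnel report.

## Interval construction

`build_blocks()` groups SNPs per chromosome by single linkage under the
strict relation |pos~i~ − pos~j~| < 1 Mb: a chain of SNPs with adjacent
gaps under the threshold forms one group regardless of its total span.
Each group becomes the interval [min(pos) − 1 Mb, max(pos) + 1 Mb],
1-based inclusive; starts are floored at 1. Two deliberate choices:

* **Distance rule, not overlap rule.** Intervals from distinct groups
  may overlap by up to 1 Mb (each is flanked by the full 1 Mb); we do
  *not* merge on overlap. Published interval sets built this way retain
  overlapping intervals, and the distance rule is the one stated, so it
  is followed literally. A gap of exactly 1 Mb does not merge.
* **Labels in genome order.** Blocks are labelled `GWAS_EOC_<n>` after
  sorting by lexicographic chromosome name then start, which is
  deterministic and matches the ordering convention of the published
  block labels.

LD proxies (r² ≥ 0.5 with an index SNP) are consumed, never computed:
`check_ld_containment()` only verifies that each proxy falls inside its
index SNP's block, mirroring the original containment check.

Internal coordinates are 1-based inclusive everywhere; BED's 0-based
half-open convention is converted exactly once, in the readers and
writers. An indel's position is its first affected base. These
conventions cannot reproduce every published interval end-coordinate
(some printed spans exceed 2 Mb by one base, and one published pair of
overlapping intervals is inconsistent with the strict distance rule), so
the packaged candidate table stores its coordinates verbatim and the
builder never forces agreement with them.

## The moderated t-test

With 10–24 samples per group, per-probe variance estimates are noisy.
`fit_moderated_t()` uses the standard empirical-Bayes hierarchical
model: the pooled residual variance of probe *g* satisfies
s²~g~ | σ²~g~ ∼ σ²~g~ χ²~d~/d with d = n₁ + n₂ − 2, and the true
variances follow a scaled inverse chi-square prior,
1/σ²~g~ ∼ χ²~d₀~/(d₀ s₀²). The posterior variance

s̃²~g~ = (d₀ s₀² + d s²~g~) / (d₀ + d)

replaces s²~g~ in the t statistic, which gains d₀ extra degrees of
freedom. The prior is estimated by moment matching on log s²~g~:
Var(log s²~g~) = ψ′(d/2) + ψ′(d₀/2), inverted for d₀ by Newton's method
on the trigamma function, with s₀² recovered from the mean. When the
observed log-variances are *under*dispersed relative to χ²~d~ alone the
moment equation has no finite solution; d₀ = ∞ is then handled as full
shrinkage to s₀² with a normal reference distribution. Probes with zero
residual variance are excluded and logged. `method = "plain"` gives the
unshrunk pooled t (the d₀ = 0 limit), and `method = "welch"` an
unequal-variance sensitivity analysis.

The adjusted p-values are Benjamini–Hochberg (the default of the
standard microarray DE toolchain); the filter retains probes with
q < 0.05 **and** |logFC| > 1, both strict, with logFC oriented HGSOC
minus FTE. Concordance between the two datasets requires joint
significance *and* matching sign — a significant flip is evidence
against a candidate, not for it.

## Overlap, ranking, consensus

*Overlap.* A gene is "in" a block if its full annotated span overlaps
the block by at least one base (computed with GenomicRanges). This
any-overlap reading is the least surprising interpretation of "located
within" and is verifiable against a brute-force scan; TSS-only or
full-containment rules would silently drop boundary genes. Multiple
probes for one gene collapse to the probe with the smallest dataset-A
q-value (ties: larger |logFC|, then probe id); a gene overlapping two
blocks keeps one record per block.

*Tissue rank.* For each gene and each resource independently, a target
tissue "occupies a top-k position" iff fewer than k non-target tissues
have strictly greater expression. k = 2 by default ("first or second
position"). Ties therefore never demote a target — the rule is
deterministic and favours inclusion on exact ties, a choice the data
source's tied zero values make unavoidable. Because the decision uses
within-resource order only, it is invariant under any strictly monotone
transform of a gene's row, and the unit mismatch between TPM-like and
FPKM-like resources is irrelevant. The shared 25-tissue panel is a
required configuration input, never hard-coded.

*Consensus.* Reviewer agreement yields the agreed class; disagreement is
resolved by an adjudication record when present and otherwise falls back
to `ambiguous` with an `unresolved` flag. The class vocabulary
(`ciliated`, `ciliated_subset`, `serous`, `ciliated_and_serous`,
`not_expressed`, `ambiguous`, `not_available`) round-trips the published
table's labels; "ciliated-positive" means any class that includes
ciliated cells. Serous-only genes count as definite but not
ciliated-positive. The block percentage is the number of distinct blocks
containing a ciliated-positive gene over the total block count,
truncated (floored) to a whole percent — matching the published
"18%" for 10 of 54 blocks, which a rounding rule would print as 19%.

## The synthetic-data generator

Real inputs (GEO series, GTEx/HPA tables, antibody images) need
downloads and manual reading, so the package generates every input with
planted ground truth. Defaults mirror the study conditions:

| parameter | default | emulates |
|---|---|---|
| SNP panel | 76 SNPs in 54 clusters (70 substitutions, 6 indels) | the risk-SNP set and its merge structure |
| dataset A | 10 FTE vs 10 HGSOC | the smaller expression series |
| dataset B | 24 FTE vs 11 HGSOC | the larger expression series |
| probes | 2000, of which 141 planted DE (one gene each) | the candidate pool |
| effect | logFC ± 2, same sign in both datasets | concordant disease signal |
| variances | s₀² d₀/χ²~d₀~, d₀ = 4, s₀² = 0.05 (log2 scale) | microarray variance heterogeneity |
| tissues | 25 shared, 4 targets, 28 planted specific genes | the two-resource rank filter |
| reviewers | A = truth; B flips with rate 0.2, flips adjudicated | independent IHC reading |

The discordance rate is not reported by any source; 0.2 is a plausible
rate for trained readers of borderline stains and exercises both
adjudication paths without dominating the labels. One seed drives
everything; each generator derives a fixed substream offset so
regenerating one input leaves the others byte-identical.

Construction forces parts of the funnel exactly: intra-cluster gaps are
drawn strictly below 1 Mb and inter-cluster gaps strictly above, so the
block count *equals* the planted cluster count; planted tissue-specific
genes carry a target-tissue row maximum in both resources while every
background gene is sabotaged in at least one, so the rank filter
recovers the planted set *exactly*; adjudications always restore the
truth, so consensus equals truth at any discordance rate. The
differential-expression stage is genuinely stochastic — recovery there
is a power statement (sensitivity ≥ 0.9 at the default effect size, FDR
≤ 0.10 at the published thresholds), not an identity.

What the generator does **not** emulate: probe-level cross-hybridisation
and batch effects, correlated genes, LD structure (proxies are inputs),
realistic tissue-expression correlation across resources, and
image-level reviewer behaviour. Passing tests therefore demonstrate that
the procedure is implemented correctly and calibrated under its stated
model, not that the model captures every property of the original
microarray or IHC data. In the same spirit, the packaged
`gwas_snps_synthetic.bed` is a synthetic stand-in for the original
risk-SNP list with the same record composition and merge structure (76
records, 54 blocks), not the original coordinates, and the headline
counts computed from it check the machinery, not the GWAS catalog.

## Numerical choices and degenerate inputs

* Trigamma inversion runs Newton from x = 0.5 + 1/y with closed-form
  guards for extreme arguments; convergence tolerance 1e−10 on the
  relative step.
* Probe rows with any missing value are dropped at read time (counted
  and reported) rather than imputed; zero-variance probes are excluded
  from testing and listed.
* Empty SNP files warn and return empty tables; an empty block list is
  an error on write (an empty BED is indistinguishable from a failed
  run).
* An all-zero tissue row fails the rank filter with an "unexpressed"
  note rather than claiming a rank among ties of zero.
* `bh_adjust()` validates its input and delegates to the stock step-up
  implementation; the test suite checks it against a literal
  from-the-definition reimplementation.

## Problem sizes

The default test suite and the acceptance script run the study-mirror
sizes (2000 probes, 10v10 and 24v11 samples, 141 planted DE genes, 25
tissues) for calibration and recovery checks, and scaled-down funnels
(500 probes, 13 SNPs, 10 clusters) for end-to-end and determinism
checks; these sizes give Monte-Carlo error small enough for the stated
tolerances while keeping a full run in seconds on one core.

## Limitations

The pipeline inherits the design limits of the original procedure: a
fixed 2-Mb window with no recombination-aware boundaries; any-overlap
gene assignment with no eQTL weighting; a rank filter that ignores
expression magnitude; and a consensus step that cannot out-perform its
reviewers. The moderated test assumes independent probes and a common
variance prior; heavy probe correlation would make the BH control
approximate. None of these choices is tunable past the exposed
thresholds, deliberately: the value of the funnel is that each stage is
simple enough to audit.
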