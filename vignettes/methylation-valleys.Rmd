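---
title: "Methods: methylation valleys, window DMRs and tissue specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation valleys, window DMRs and tissue specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvalley)
library(data.table)
```

This vignette is the package's account of its models and the decisions
behind them: what each statistic assumes, which thresholds matter and why
they default to what they do, what the synthetic generator does and does
not emulate, and where the design was genuinely open.

## Data model and coordinates

The atomic observation is a strand-resolved cytosine with its sequence
context (CG, CHG or CHH — the three contexts methylated by distinct plant
pathways) and methylated/unmethylated read counts. Cytosine positions are
stored 1-based, as in the cytosine-report format they come from; every
interval (window, DMR, valley, gene) is 0-based half-open, the BED
convention, and positions are converted on the fly for interval queries.
The two cytosines of a symmetric CG dinucleotide are kept as independent
sites: the report format is per-strand, and no symmetrisation rule is
assumed. Zero-coverage sites are retained at load time and removed by each
statistic's own coverage rule, so one loaded object serves every analysis.

## Two different "methylation levels"

Two summaries that are often conflated are kept deliberately distinct:

- the **read-weighted level** Σ meth / Σ (meth + unmeth), used for global
  and windowed summaries and for metagene bins. It is coverage-robust —
  a site sequenced 40× counts for more than one sequenced 2× — and is the
  field's standard for WGBS summaries. Its coverage floor defaults to 1
  (every observed read informs it).
- the **unweighted per-site mean**, used by the valley scan, where the
  defining quantity is "the average methylation level of all C sites
  within the window". Here each observed site counts equally, and a
  coverage floor matters: a site seen twice has a noisy level estimate.
  The floor defaults to 4, matching the per-base coverage rule used
  elsewhere in the pipeline.

Requesting a level over a region with no qualifying site is an explicit
error, never silently 0 — an unobserved region is not an unmethylated one.
Windowed summaries return missing values for empty tiles for the same
reason.

## Methylcytosine calling

Whether a cytosine "is methylated" is a detection question against the
combined bisulfite non-conversion and sequencing error rate. A site with
coverage ≥ 4 is tested with the one-sided binomial tail
P(X ≥ meth | n = coverage, p = error) at error = 0.005 by default, and
calls are controlled at Benjamini–Hochberg q ≤ 0.05 across all tested
sites. This is the long-standing convention for WGBS mC calling; the
context proportions of called mC (the familiar CG/CHG/CHH pie) follow
directly. The error rate is exposed because it should come from the
experiment (lambda spike-in or chloroplast non-conversion) when available.

## Window DMR calling

Differential methylation between two tissues is tested per 200 bp tile.
Within each group, replicate read counts are pooled by summation over the
sites of the tested context whose per-sample coverage is ≥ 4; sites may
qualify in one replicate and not another, and the site count of a window is
the number of distinct positions qualifying in at least one sample. The
test is the uncorrected Pearson χ² (1 df) on the 2×2 table
(group × methylated/unmethylated reads); pooling plus χ² means no
between-replicate dispersion model, which is exactly the assumption the
pooled-count test encodes — callers wanting replicate-level inference
should use a beta-binomial model, which is out of scope here.

Windows are tested only when the site threshold is met in **both** groups
(a one-sided rule would test windows with no information on one side) and
the table is non-degenerate; degenerate windows (a zero margin, e.g. both
groups fully unmethylated) are skipped and excluded from the adjustment
family rather than being assigned p = 1, so they neither dilute nor inflate
the BH correction. Adjustment is Benjamini–Hochberg per context across all
tested windows genome-wide; "q" procedures vary between published tools,
and BH is chosen as the deterministic, testable one. A window is a DMR when
q ≤ 0.05 **and** the absolute difference of pooled levels meets the
context's effect floor (CG/CHG 0.25, CHH 0.15, all-C 0.20) with the
context's site minimum (5/5/15/20). The all-C variant is a fourth
selectable context, not part of the three standard calls.

Gene association uses the upstream-2kb + body + downstream-2kb rule with a
1 bp overlap criterion, flanks clipped at chromosome ends.

## Valley detection

The scan is a 1 kb window advanced by 200 bp; a window qualifies when its
unweighted per-site mean over **all** cytosine contexts is below 5% and it
contains at least 5 qualifying sites (an a-priori guard against calling
valleys from near-empty windows — the defining publication-style rule
states no site minimum, so the guard is configurable). Partial trailing
windows are not evaluated: a truncated window would change what "mean of a
1 kb window" means. Qualifying windows overlapping by ≥ 1 bp are merged by
union into maximal regions, so a valley is always a union of qualifying
windows, is at least 1 kb long, and snaps to the 200 bp step grid — which
also bounds the edge error against a planted valley at roughly one step on
each side. Valleys are called per tissue on the replicate-pooled methylome
(counts summed per site), since a valley map is a property of a tissue, not
of a replicate.

A gene is a **DMV gene** when the cumulative intersection of its body with
the valley union covers ≥ 80% of the gene, boundary inclusive. Cumulative
(rather than single-valley) overlap is the natural reading once windows are
merged; inclusiveness makes the boundary deterministic.

## Tissue specificity and enrichment

The tau index is computed on raw abundances: with only two tissues every
per-gene monotone transform leaves the τ ≥ 0.99 classification a function
of min/max alone, so transformation would add an assumption without
changing the answer. An all-zero gene has no defined τ and is excluded, not
scored 0. The abundance floor (max ≥ 1 FPKM, configurable to 0) exists
because τ of (0.02, 0) is exactly 1; without a floor, noise-only genes
dominate the "specific" class. Argmax ties are excluded and reported. The
fold-change classification is boundary-inclusive (≥ 2) with a 0.01
pseudocount so zero denominators stay finite.

Enrichment is the hypergeometric upper tail including the observed overlap,
P(X ≥ k), computed via the log-space distribution function. The universe is
a declared parameter: the pipeline defaults to genes with defined τ
(expressed somewhere), because membership in both compared sets presupposes
an expression measurement; all annotated genes is the alternative. The
choice can move p by orders of magnitude and therefore is never implicit.

## Metagene profiles

Profiles use 2 kb flanks in 20 fixed-width bins each and gene bodies
rescaled to 60 bins — chosen as round, conventional values; all three are
parameters. Bin pooling is read-weighted across genes (reads summed per
bin), not a mean of per-gene means: sparse genes then contribute in
proportion to their information, and the estimator is deterministic and
testable. A site's body bin is floor((pos − start)/length × 60) from the
gene's 5′ end; minus-strand genes use the exact mirror of the plus-strand
assignment, which makes profile reversal under strand flips exact rather
than approximate. Genes shorter than the body bin count are skipped with a
warning. The "constitutive" reference set in the pipeline is genes with
defined τ ≤ 0.5 passing the abundance floor.

## The synthetic study

The generator emulates the statistical structure the estimators assume,
with every condition stated up front:

- 3 chromosomes × 200 kb of uniform random sequence; every cytosine on both
  strands catalogued with the context derived from its strand-relative
  trinucleotide (cytosines within 2 bp of a 3′ end have no complete
  trinucleotide and are omitted rather than given an invented context).
- compartments with per-context methylation means — background
  0.60/0.45/0.08 (CG/CHG/CHH), TE-like blocks 0.95/0.80/0.12, gene regions
  0.25/0.08/0.03, valleys 0.005 — a plant-like landscape in which TE-dense
  regions are hypermethylated and gene regions carry mostly CG gene-body
  methylation.
- per-valley length 3 kb, placed on the 200 bp step grid. The detector's
  resolution bounds its boundary overshoot at ~1 step per side, so 3 kb
  keeps the per-valley Jaccard criterion (≥ 0.9) a test of correctness
  rather than of snap-to-grid luck; lengths ≥ 2 kb are the realistic range.
- 60 planted CG-differential 200 bp windows at 0.75 vs 0.25 (|Δ| = 0.5).
- per site and sample, the true level is a Beta draw around the compartment
  mean with concentration 50 (so replicates differ realistically), coverage
  is Poisson(10) — the study-scale mean depth — and methylated reads are
  binomial. Three replicates per tissue.
- expression: log-normal baselines (meanlog log 20, sdlog 1, a realistic
  FPKM spread) with the class fixing the cross-tissue ratio exactly —
  exclusive 0 (τ = 1), preferential 0.005 (τ = 0.995), constitutive 1
  (τ = 0) — and root-exclusive genes planted inside valleys so the
  valley–specificity association is designed, not emergent.

What the generator does **not** emulate: mappability and coverage
autocorrelation, sequence-composition bias, linked sites within reads,
partial methylation domains, realistic TE sequence, or any coupling between
methylation and expression noise. A green recovery test therefore
establishes that the estimators invert the generative model they assume —
not that they are robust to artefacts real libraries contain.

Determinism: the whole dataset is a function of (plan, seed); sample
streams are namespaced by (seed, tissue, replicate), and identical seeds
give byte-identical files.

## Numerical and degenerate-input choices

- χ² is computed in doubles via n(ad − bc)²/(r₁r₂c₁c₂), overflow-safe for
  genome-scale counts; p-values from the χ² upper tail, 1 df, no continuity
  correction (the pooled counts are large where it matters).
- BH is the textbook step-up (cummin from the largest p), clipped to
  [0, 1], order-preserving.
- hypergeometric tails come from the log-space distribution function, so
  p = 2e-16-scale values are representable.
- empty inputs error early and explicitly (no data ≠ zero signal); interval
  sets with unknown chromosomes are rejected rather than reordered
  silently.

## Known limitations

- No beta-binomial/overdispersion DMR model: pooled χ² understates
  between-replicate variance when replicates truly disagree.
- Valley calls depend on the coverage floor and site minimum in sparse
  genomes; both are exposed parameters and should be revisited below ~5×.
- With two tissues, τ degenerates to 1 − min/max; the index is most
  informative with more tissues.
- The pipeline treats the first two tissue labels as the comparison pair
  and expects exactly two tissues.
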