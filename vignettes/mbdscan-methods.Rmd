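---
title: "Window-based differential methylation calling with MBDscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MBDscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MBDscan analyses enrichment-based methylome sequencing (MBD-seq / MiGS),
where genomic DNA fragments are captured by the methyl-CpG binding domain of
MBD2 and sequenced, so that local read depth is the evidence for DNA
methylation. This vignette documents the statistical model behind each stage,
the tunable parameters and their defaults, the behaviour of the synthetic
data generator, and the numerical decisions that a user re-deriving results
should know about.

```{r, eval = FALSE}
library(MBDscan)
```

## From fragments to a filtered window count matrix

Aligned read positions tag only the 5' end of each captured fragment, so
reads are first extended to the average fragment length
(`extendFragments()`; a fragment on the minus strand grows leftwards from
its 3' coordinate). The genome is tiled in non-overlapping 50-bp windows
(`tileWindows()`; the last window of a chromosome may be truncated and is
kept, so the tiling covers the genome exactly). The count for a window and
sample is the average per-base fragment depth over the window, rounded half
away from zero (`countCoverage()`); truncated windows average over their
actual width. Rounding direction is a convention, not a model choice — we
round 0.5 up so single-fragment windows are never erased.

Most of the genome carries no methylated signal, only scattered background
reads. The filter (`poissonFilter()`) formalises "no more signal than even
coverage would give": each sample's rate is estimated as its mean count per
window, $\hat\lambda_s = \sum_w c_{ws} / n$, and the minimal significant
count is

$$c_s = \min\{c \in \mathbb{N}: P(\mathrm{Pois}(\hat\lambda_s) \ge c) \le \alpha/n\},$$

a Bonferroni correction across the $n$ windows at family-wise level
$\alpha = 0.05$ by default. A window is retained when at least one sample
reaches its threshold. Bonferroni was chosen over per-window FDR because the
filter's job is to bound the absolute number of noise windows entering the
mixture fit; both the level and the rule are configuration, and the filter
report logs $\hat\lambda_s$ and $c_s$ per sample. Estimating
$\hat\lambda_s$ from the window counts themselves (rather than from read
totals and fragment length) is equivalent under the even-coverage
assumption and requires no read metadata.

## Signal deconvolution: a three-Poisson mixture

Retained window counts for one sample are modelled as a mixture of three
Poisson components,

$$c \sim \sum_{k=1}^{3} \pi_k\, \mathrm{Pois}(\lambda_k), \qquad
\lambda_1 \le \lambda_2 \le \lambda_3,$$

interpreted as unmethylated background, ambient/intermediate signal, and
methylated enrichment. `fitThreePoisson()` runs EM to a maximum a
posteriori estimate under weak conjugate priors — Gamma(1, $10^{-3}$) on
each rate and a symmetric Dirichlet(1) on the weights — which is maximum
likelihood up to a negligible shrinkage; the penalised log-likelihood trace
is stored and is non-decreasing by construction. A full posterior sampler
would add nothing here because only the per-window component posteriors are
consumed downstream.

Initialisation is deterministic (rates at the 25th/75th/99th percentiles of
the counts plus 0.1, weights 0.6/0.3/0.1), so a fit is a pure function of
its input and permutation-invariant. Convergence is declared when the
relative change of the objective falls below `tol = 1e-8`; `maxIter = 500`;
weights and rates are floored at $10^{-6}$. The EM operates on the
tabulated count distribution, so its cost is governed by the number of
distinct count values, not the number of windows.

The probability that a window is methylated is the posterior weight of the
highest-rate component,

$$p_{\mathrm{meth}}(c) = \frac{\pi_3 \mathrm{Pois}(c;\lambda_3)}
{\sum_k \pi_k \mathrm{Pois}(c;\lambda_k)},$$

computed in log space. Two practical complications arise when the data hold
fewer than three real regimes, and both are handled explicitly:

* **Top-component collapse.** When retained counts are bimodal (background
  vs methylated — exactly the sharp-difference situation), the two top
  components settle on nearly the same rate and split the methylated weight
  arbitrarily, making the $\lambda_3$ posterior alone meaningless.
  Components whose rate lies within `collapseSd = 2` Poisson standard
  deviations of $\lambda_3$ cannot be resolved at single-window counting
  noise, so `methylationProbability()` sums their posteriors. A relative
  (ratio-based) criterion was rejected because the split point between two
  collapsed components is arbitrary and can fall on either side of any
  fixed ratio.
* **Full collapse.** When *every* retained window of a sample is enriched
  (purely quantitative differences, or methylation shared by both groups),
  all three components collapse onto one high rate. Within the mixture
  there is then no background to contrast against, so `posteriorMatrix()`
  falls back to an equal-weight two-point contrast between the sample's
  even-coverage rate $\hat\lambda_s$ (from the filter) and the collapsed
  rate — provided the collapsed rate reaches the sample's filter threshold.
  Isolated single-regime fits without filter context keep the plain (then
  constant) mixture posterior.

Binary status is `p >= tau` with `tau = 0.5`; the tie goes to methylated.
Windows removed by the filter are fixed at posterior 0 — the filter has
already judged them noise, and segmentation must not resurrect them.

## Segmentation and candidate regions

Per sample and chromosome, maximal runs of methylated windows are merged
across gaps of at most `maxGap = 2` windows (100 bp), and merged runs with
fewer than `minWindows = 2` methylated windows are dropped
(`statusRuns()`, `scanSegments()`). For binary statuses this gap-tolerant
run merging is the simplest scan statistic producing "consistent
methylation allowing small gaps"; both parameters are configuration because
no canonical values exist. Segments never cross chromosome boundaries.

Overlapping segments from any samples are unioned into maximal candidate
regions (`candidateRegions()`), the units of differential testing. A
sample's status over a candidate is methylated when at least half
(`majority = 0.5`) of the candidate's windows are methylated in that
sample; the majority rule makes the per-sample pattern robust to a
straggling window at a region edge.

## Differential testing and DMR classes

Each candidate is tested with a linear mixed-effects model at window level
(`testRegion()`):

$$\log_2(c_{ws} + 1) = \mu + \beta\,[s \in B] + b_s + \varepsilon_{ws},
\qquad b_s \sim N(0, \sigma_b^2),$$

where the random per-sample intercept $b_s$ absorbs library-size and
biological sample effects. The reported p-value is the Satterthwaite-df
t-test on the group term (lmerTest, REML). With three samples per group the
group contrast carries roughly four between-sample degrees of freedom, and
a 1-df likelihood-ratio chi-square is badly anti-conservative at this size
(type-I error near $P(|t_4| > 1.96) \approx 0.12$); the Satterthwaite test
is calibrated, which the suite verifies by simulation ([0.03, 0.07] at
nominal 0.05). When the mixed fit is singular (random-effect variance at
zero) or fails, the test falls back to a Welch t-test on per-sample region
means and flags the region. Degenerate all-equal candidates get p = 1.

Fold change is reported on the linear count scale as
$(\bar c_B + 0.5) / (\bar c_A + 0.5)$ of per-sample region means;
the pseudocount (configurable) keeps zero-count groups finite. P-values are
Benjamini–Hochberg adjusted across candidates (`adjustPvalues()`, delegating
to `stats::p.adjust`), with an FDR threshold of 0.05.

A significant candidate is classified (`classifyDmr()`) as

* **sharp 01** — all group-B samples methylated, all group-A unmethylated
  (hypermethylated in the fibrotic group);
* **sharp 10** — the converse (hypomethylated);
* **quantitative** — all samples of both groups methylated, with the counts
  carrying the significant difference; direction then follows the fold
  change;
* **excluded ("inconsistent")** — any mixed pattern. Neither printed
  definition covers mixed patterns, so they are retained in the output
  table with a reason code rather than silently forced into a class.

Sharp DMRs are the unit of all downstream annotation, since quantitative
differences can also reflect copy-number changes. The heatmap matrix
(`heatmapMatrix()`) is $\sqrt{\text{total DMR count}/\text{windows}}$ per
sample, and `countByChromosome()` tallies hyper/hypo counts per chromosome.

## Annotation rules

Promoters are 1000 bp upstream to 500 bp downstream of the TSS
(strand-aware, clipped to the chromosome). The printed "+1000 bp to −500 bp"
convention is ambiguous about sign; the conventional asymmetric
upstream-heavy reading is used and both extents are configurable. The
3' end window is symmetric, ±1000 bp around the TTS. A DMR's category is the
highest-priority overlap pooled across all genes:
promoter > 3' end > exon > intron > intergenic, with introns derived as
transcript span minus exons. CpG-island context uses edge-to-edge distance
$d$ to the nearest merged island: island ($d = 0$), shore
($0 < d \le 2000$), shelf ($2000 < d \le 4000$), open sea ($d > 4000$).
Edge distance (not midpoint) is used; the bands are half-open so every
locus gets exactly one label. Both classifiers are verified against
per-base brute-force oracles in the test suite.

## Expression integration

Genes with at least one sharp DMR of priority category promoter are joined
to an externally produced differential-expression table (gene, linear fold
change B vs A, BH-adjusted p). A gene with adjusted p below 0.05 is
**inverse** when promoter hypermethylation (01) pairs with a fold change
below 1, or hypomethylation (10) with a fold change above 1. Genes, not
DMRs, are the output unit; a gene whose promoter DMRs disagree in direction
is marked discordant and never flagged inverse. The DE table is consumed,
never computed — the pipeline makes no claims about expression inference.

## The synthetic-data generator

`simulateBundle()` produces a complete toy study: a genome of
`chr1..chrN`, non-overlapping gene models with 1–8 exons (BED12
conventions), CpG islands (a configurable fraction inside promoters),
planted truth regions, window counts, and a DE table.

Counts are generated directly at window level:
$c_{ws} \sim \mathrm{Pois}(f_s\, r_{g(s)}(w))$ with per-sample size factors
$f_s$ drawn log-uniform on [0.7, 1.4] and rates from the planted region
covering the window (background elsewhere). Default rates are background
0.3, methylated 25, quantitative pair (25, 60) counts per window — chosen
so mixture components separate cleanly at desk scale; the true dynamic
range of MBD enrichment is not established, so these are testability
choices, not claims about real libraries. Region kinds are sharp01,
sharp10, quantitative, and shared-methylated decoys; regions are
window-aligned and non-overlapping, and sharp regions destined for inverse
genes are anchored at promoter midpoints while all others avoid promoters
entirely, so the planted inverse set is exactly the recoverable one.
Expression surrogates are planted directly (inverse genes get
opposite-direction fold changes and adjusted p < 0.05; other genes hover at
fold 1 with p ≥ 0.05) because the pipeline only consumes them.

What the generator does **not** emulate: read-level artefacts (mapping
bias, duplicates, fragment-size spread), CpG-density-dependent capture
efficiency, overdispersion beyond Poisson, copy-number variation, and
correlated windows. Passing the planted-truth validations therefore shows
the statistical machinery is correct under its own generative assumptions —
it does not certify performance on real libraries, where overdispersion and
capture bias will loosen the mixture separation.

## Problem sizes and validation design

The validation suite runs the full pipeline on a 10-Mb toy genome
(200,000 windows, 3 vs 3 samples) with 200 planted sharp regions of 4–10
windows and 50 shared-methylated decoys, and checks sensitivity ≥ 0.90,
false-discovery proportion ≤ 0.10 and ≥ 90 % direction agreement; a null
run (shared methylation only) must call ≤ 5 % of candidates; a purely
quantitative run (rates 25 vs 60) must classify ≥ 90 % of its calls
quantitative and none sharp. Mixture recovery is checked at $10^5$ windows
from $\pi = (0.7, 0.2, 0.1)$, $\lambda = (0.2, 5, 25)$ with 5 % relative
tolerance per rate. Exact-equivalence checks compare the interval machinery
against brute-force oracles: per-base feature classification, minimum
island distance, exhaustive run enumeration (all status vectors to length
10 across the parameter grid, plus sampled length-20 vectors), naive
per-base pileup, and textbook BH. `scripts/acceptance.R` recomputes all of
these end to end from a fresh simulation under a caller-supplied seed.

## Known limitations

* Poisson (not negative-binomial) counts throughout: real MBD-seq windows
  are overdispersed; the mixture rates would widen and the filter would
  retain more noise windows on real data.
* The scan is binary; a probabilistic (HMM-style) segmentation could use
  posterior magnitudes instead of thresholded statuses.
* Cross-sample candidate unification is a simple interval union; partially
  overlapping events in different samples become one testing unit.
* The mixed model assumes independent windows within a region; positive
  autocorrelation of coverage would make region p-values optimistic on
  real libraries.
* No model selection over the number of mixture components; three is fixed
  by design, with collapse handling standing in for fewer-regime data.
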