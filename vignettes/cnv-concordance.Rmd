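---
title: "Methods: multi-platform CNV concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-platform CNV concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconcord)
```

# The problem

Gene copy-number variation (CNV) in tumors is measured by technologies with
incompatible output scales: microarray calling tools emit three-state calls
(deletion / normal / amplification), while hybridization CNV panels and
droplet digital PCR (ddPCR) emit continuous copy numbers per diploid
genome. Bulk tumor tissue adds a further complication: a sample is a
mixture of tumor and stromal cells, so even a clean single-copy gain in
every tumor cell reads as a non-integer value diluted toward 2. This
package implements the statistical machinery for asking, on a paired
tumor/normal cohort measured by several such platforms at once: *how well
do the platforms agree, are their disagreements systematic, and which genes
actually change copy number in tumors?*

# The data model

Everything operates on one tidy table: one row per
(patient, tissue, method, gene) measurement, where each method is either
quantitative (a non-negative copy number) or categorical (a three-state
call). Missing measurements are absent rows, never sentinels; every
pairing operation is complete-case, using only the (patient, tissue)
samples observed by both methods being compared. The canonical iteration
order is ascending patient id (then tissue), which makes every output
deterministic. Nothing in the cross-platform design requires matrices: a
keyed long table keeps the pairing logic explicit and testable.

# Discretization

Quantitative values are converted to calls by a threshold rule: values in
[1.5, 2.5] — boundaries inclusive — are *normal* (2 copies), below 1.5
*deletion*, above 2.5 *amplification*. This rule is total and monotone. An
alternative vendor-style band rule accepts a value only within ±0.4
(inclusive) of its nearest integer, maps the integer to a call (≤1
deletion, 2 normal, ≥3 amplification) and *excludes* everything else, i.e.
exactly the open intervals (n + 0.4, n + 0.6). Two conventions had to be
fixed where guidelines are silent: exact halves round away from zero (so
2.5 has an unambiguous nearest integer, 3 — at the default band it is
excluded anyway, being 0.5 from it), and excluded values are dropped from
categorical analyses rather than carried as a fourth category.

# Quality filters

Normal (non-tumor) tissue should be diploid, so an assay's normal-tissue
behavior is its internal control. Two filters follow from that:

* **Normal-median filter.** Per (method, gene), the median of the
  normal-tissue copy numbers must lie in [1.5, 2.5] (inclusive; even
  counts use the midpoint convention). Failing groups are excluded from
  all downstream analyses. Tumor values never enter the decision, so a
  genuinely amplified gene cannot disqualify its own assay.
* **Reference-gene adequacy.** ddPCR copy numbers are ratios to a
  reference gene; a reference that is itself copy-number variable drags
  every normalized value away from 2. The check pools all normal-tissue
  values of the methods sharing a reference configuration and flags the
  configuration when the fraction outside [1.5, 2.5] exceeds a threshold.
  The threshold defaults to 0.5 — "a significant portion" made
  operational as a majority — and is a parameter precisely because any
  single number here is a judgment call.

# Categorical agreement: PABAK

For two call sets cross-tabulated over k categories with observed
agreement P₀ (the diagonal share), the prevalence- and bias-adjusted kappa
is

$$\mathrm{PABAK} = \frac{k P_0 - 1}{k - 1}.$$

Unlike Cohen's kappa it does not depend on the marginal distributions, so
a cohort where nearly every call is "normal" (the usual situation for most
panel genes) cannot crush the coefficient through prevalence alone. Design
choices:

* `k` is the number of *defined* categories (3), not the number observed
  in a particular table — otherwise sparse tables would silently switch
  formulas. A binary mode (k = 2, giving 2P₀ − 1) is available for
  two-category reductions.
* Cells of the per-(gene, pair) matrix with no aligned calls are reported
  as missing with n = 0, never as zero agreement; medians are taken over
  available cells only.
* Gene rows are ordered by decreasing per-gene median PABAK, the standard
  panoramic display for such matrices.
* Agreement bands use the conventional cut-points anchored at the
  substantial interval: negative (<0), poor [0, 0.20], moderate
  (0.20, 0.60], substantial (0.60, 0.80], near-perfect (0.80, 1]. The
  bands label displays only; no computation consumes them.
* Tumor and normal samples are pooled into one table per (gene, pair) by
  default, with a tissue filter for separate analyses — the pooled form
  is what per-gene agreement matrices usually show.

# Quantitative agreement: Passing–Bablok and relative discrepancy

Passing–Bablok regression fits y = k·x + b without assuming error-free x:
the slope is a shifted median of all pairwise slopes
S₍ᵢⱼ₎ = (yⱼ − yᵢ)/(xⱼ − xᵢ). Following the original prescription: pairs
with equal x contribute no slope; slopes exactly −1 are discarded; with K
the count of slopes below −1, the estimate is the K-shifted median of the
N sorted slopes, which makes the estimator invariant to swapping the
axes. The intercept is median(y − k·x). The slope confidence interval
takes the sorted slopes at ranks round((N − C)/2) + K and its mirror,
with C = z₁₋α/₂ √(n(n−1)(2n+5)/18); rank rounding is round-half-to-even.
The intercept interval re-evaluates the residual median at the two slope
bounds. Proportional bias is declared when 1 falls outside the slope
interval, constant bias when 0 falls outside the intercept interval.

Degenerate regimes are handled explicitly rather than clamped:

* n < 3, constant x, or no defined pairwise slope: error.
* More than half the slopes below −1 (methods negatively related): the
  shifted-median rank leaves 1..N and the estimator is undefined — error.
  Method-comparison data should never be in this regime.
* Very small n at the requested α: the CI ranks can leave 1..N; the
  intervals and both bias flags are then reported as `NA` with a warning
  advising more points, because clamping ranks to the extremes would
  fabricate coverage.

Bias flags answer "is the disagreement systematic?", not "is the
disagreement small?". The relative discrepancy
dᵢ = |yᵢ − xᵢ| / max(xᵢ, yᵢ) ∈ [0, 1] (0/0 defined as 0) captures the
scatter itself; its median and quartiles use the linear-interpolation
quantile convention (`quantile()` type 7). The absolute value is used: the
quantity is a magnitude, and its boxplot summaries are non-negative by
construction. Panel comparisons pool all (gene, patient, tissue) points
shared by the two methods into a single fit — matching the one-scatter-
per-pair display this analysis is usually read from — with per-gene
fitting available by passing a single gene.

# Differential copy number

Per gene and quantitative platform, a two-sided paired Wilcoxon
signed-rank test compares tumor vs normal. Zero differences are discarded
before ranking (the classic convention — stated explicitly because the
exact-enumeration tests need a fixed convention). The exact null
distribution is used when ≤ 25 non-zero differences remain and their
absolute values are tie-free; otherwise the normal approximation with
continuity correction. If all differences are zero the test degenerates:
p = 1 with a warning, not an error.

Because the same hypothesis is tested once per platform, the per-platform
p-values are pooled by the plain harmonic mean m / Σ(1/pᵢ) over the m
platforms with data (absent platforms are skipped, never imputed); the
harmonic mean is dominated by its smallest input and always lies between
the minimum and maximum. This is deliberately the plain harmonic mean,
not the calibrated harmonic-mean-p procedure — the pooled column of the
published table this package models arithmetically matches the plain
version. Holm's step-down correction is then applied across genes only
(m = number of genes in the table); it is the package's only
multiple-testing layer. Reports annotate 0.05 < p < 0.1 as trend-level;
the annotation never affects computation. A Spearman rank correlation
(average ranks, asymptotic t p-value) is included as a minor descriptive
statistic for burden-vs-covariate questions.

# The cohort simulator

The generator exists so that every stage has a ground truth. Its defaults
describe the study conditions it emulates — a small clinical benchmarking
cohort — and were chosen once:

* 13 patients with paired tumor/normal tissue; an 87-gene panel of
  cancer-associated genes (the size of a commercial CNV assay).
* Latent tumor copy numbers drawn per patient × gene from
  P(CN = 0..4) = (0.03, 0.13, 0.74, 0.07, 0.03): mostly diploid, with
  deletions about 1.6× more frequent than amplifications, the ratio such
  panels report in high-grade serous ovarian carcinoma. Normal tissue is
  CN = 2 throughout (no germline events by default).
* Tumor purity per patient from Uniform(0.5, 0.9) — typical bulk-resection
  purities — entering as linear dilution,
  effective = purity·CN + (1 − purity)·2: the simplest mixing model
  consistent with intratumor heterogeneity producing non-integer bulk
  values. A diploid gene reads exactly 2 at any purity.
* Platforms: two categorical microarray callers that share one latent
  noisy signal (sd 0.1 copies — they process the same raw data) and each
  apply a 5% symmetric misclassification channel; one quantitative
  hybridization panel with +0.5 copies constant bias (quantitative panels
  in this setting read systematically above PCR) and noise sd 0.2; two
  ddPCR chemistries with identity parameters and noise sd 0.15.
* Gaussian measurement noise is truncated at 0, since copy numbers cannot
  be negative; the truncation slightly biases values near 0 upward, which
  matters only for homozygous deletions at high purity.

Given a seed the generator is byte-deterministic. What it does *not*
emulate: probe- or droplet-level error structure, locus-specific assay
difficulty, subclonal architecture beyond the single purity parameter, or
correlated errors between quantitative platforms (a shared-noise term for
the callers is the only cross-platform correlation). Tests passing on
simulated cohorts therefore validate the statistical machinery — they do
not certify any particular laboratory platform.

# Verification strategy and problem sizes

The test suite checks each statistic against an independent brute-force
oracle: PABAK against its closed form on every 3×3 table with total
count ≤ 6 (exhaustive enumeration); the Passing–Bablok slope and intercept
against direct pairwise-slope enumeration on hundreds of random small
scatters (n ≤ 8) plus exact linear data; the Wilcoxon p against full
enumeration of all 2ⁿ sign assignments; pooling and correction against a
published seven-gene table whose per-method p-values are injected as
inputs. Stochastic properties use seeded replicates at desk scale: 100
replicates of 50-point platform pairs for bias-flag recovery, 200
replicates of 13-patient × 8-gene null cohorts for family-wise error
control. One honest caveat surfaced by the published-table check: a
harmonic mean recomputed from *printed* (3-decimal) per-method p-values
can differ in the final digit from a pooled value the original authors
computed at full precision, and interval analysis shows the printed inputs
of one gene cannot reproduce its printed pooled value; the package reports
the recomputed number.

# Limitations

* PABAK, being prevalence-independent, is also blunt: it cannot localize
  *which* category drives disagreement. The underlying contingency tables
  are retained for that.
* Passing–Bablok assumes an approximately linear relation and positively
  related methods; it is undefined (and errors) otherwise.
* The harmonic mean is used as a descriptive pooling rule, as in the
  analysis it models; it is not a calibrated combined test, and the Holm
  layer treats pooled values as ordinary p-values.
* Complete-case pairing can make different cells of the same agreement
  matrix rest on different sample subsets; cell n's are always reported.
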