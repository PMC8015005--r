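---
title: "Missing-value-aware differential abundance testing with PolyDA"
author: "PolyDA maintainers"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-value-aware differential abundance testing with PolyDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolyDA)
```

# The problem

Label-free quantitative proteomics and metabolomics deliver a feature x
sample matrix of (log) abundances in which a substantial fraction of cells
is missing -- below the detection limit, lost during sample handling, or
skipped by stochastic precursor selection. Missingness is informative: a
protein quantified in every replicate of one condition and in none of the
other is often exactly the kind of on/off regulation an experiment is
after, yet it is invisible to any test that needs two variances. Imputing
zeros (or any constant) manufactures artificial variance structure instead.

PolyDA tests each feature between two conditions with five complementary
tests and combines their false discovery rates into one unified per-feature
FDR:

* **Miss test** -- the missingness test described below; the only test that
  uses absence itself as evidence.
* **moderated t** -- empirical-Bayes variance shrinkage across features.
* **rank products** -- nonparametric consistency of ratio ranks across
  replicate pairs.
* **permutation test** -- per-feature randomization null with
  low-replicate augmentation.
* **plain t** -- Welch / paired Student reference; reported, but excluded
  from the unified FDR because it underestimates the FDR for fewer than
  about five replicates.

# Data model

`QuantExperiment` extends `SummarizedExperiment`: one `"quant"` assay of
log2 abundances with `NA` for missing cells, and a column design assigning
every sample a condition and a replicate index (1..r, gap-free, which is
what paired analyses pair on -- the input data carry no other pairing key).
Zero is a legitimate log-abundance and is never confused with missing. A
`Comparison` is an ordered pair of conditions; positive log-ratios mean
higher abundance in the treatment condition.

Preprocessing mirrors common label-free practice: technical replicates are
summed on the raw scale, values are log2-transformed (non-positive cells
become missing by default), each sample column is median-centered, and
features can be filtered by a minimum number of observed values and by
per-feature annotations such as unique-peptide counts.

# The Miss test

Let $p_{NA}$ be the fraction of missing cells in the whole matrix. Under
the null hypothesis that values are missing at random, the number of
missing values among $r$ replicates is binomial,

$$b_i = \binom{r}{i} p_{NA}^i (1 - p_{NA})^{r-i},$$

and the absolute difference $k$ of missing counts between two conditions
has probability

$$P_0 = \sum_j b_j^2, \qquad
  P_k = 2 \sum_{j=0}^{r-k} b_{j+k} b_j \; (k \ge 1).$$

The $k = 0$ term is self-symmetric and must not be doubled; with the
factor 2 applied only for $k \ge 1$ the vector sums to one and reproduces
the canonical example at $r = 3$, $p_{NA} = 1/2$: out of the $2^6 = 64$
equally likely missingness patterns, 20/30/12/2 cases give $k$ = 0/1/2/3,
i.e. probabilities 5/16, 15/32, 3/16, 1/32.

Presence/absence alone ignores abundance. The test therefore scans 100
detection-limit scenarios: the thresholds are the $q/100$ empirical
quantiles ($q = 0..99$) of all observed values; in each scenario every
value strictly below the threshold is treated as missing, $p_{NA}$ is
recomputed over the whole matrix, and each feature's $k$ is recounted on
the censored data. The feature's p-value is the smallest $P_k$ across
scenarios, multiplied by $r + 1$, and capped at 1. The scan couples
missingness to abundance: a feature whose observed values in one condition
are all high while the other condition is absent or low reaches a large
$k$ already at a low threshold, where $P_k$ is small.

Numerical choices worth knowing:

* The grid includes $q = 0$ (the uncensored data) and excludes the top
  quantile, which would censor everything and make $P_k$ degenerate.
  Empirical quantiles use R's default (type 7) interpolation.
* "Below the threshold" is strict; a value equal to the threshold
  survives. This makes results reproducible to the bit.
* Unequal replicate counts $r_A \neq r_B$ are handled by direct
  convolution of the two binomials, $P(|X - Y| = k)$; the multiplier
  becomes $\max(r_A, r_B) + 1$. This reduces exactly to the equal-count
  formula when $r_A = r_B$.
* $k$ is unsigned; the test has no directional variant.

## What the null distribution looks like

The Miss test's p-values are *discrete and conservative*, not uniform.
The capping rule forces a point mass at $p = 1$: at $r = 5$, a fully
observed feature with $k = 0$ in every scenario has
$\min_s P_0(s) \cdot 6 > 1$, and roughly half of the features of a
pure-noise matrix end there. The low tail is mildly sub-uniform (about 3%
of null features fall below $p = 0.05$ in our calibration runs), which is
the side that matters for FDR control: across seeded pure-noise grids,
features with Benjamini-Hochberg FDR < 0.1 occur in about 5% of datasets
and never more than one per dataset. A two-sided Kolmogorov-Smirnov
comparison against Uniform(0,1) rejects on the mass at 1 -- by
construction, for any implementation of this capping rule -- so
`uniformityCheck()` is most informative for tests with genuinely
continuous statistics (it passes for the moderated t on null data).

# The other tests

**Moderated t.** Per comparison, each feature's two-group effect
$\Delta_g$ and pooled residual variance $s_g^2$ (observed values only,
$d_g$ residual df) feed the hierarchical model
$s_g^2 \sim s_0^2 F(d_g, d_0)$. Hyperparameters are estimated by moment
matching of $\log s_g^2$ with digamma/trigamma identities (Newton
inversion of the trigamma function); when the log-variances show no excess
dispersion beyond sampling noise, $d_0 = \infty$ and $s_0^2$ is the mean
sample variance. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t = \Delta_g / (\tilde s_g u_g)$ with $d_g + d_0$ df (capped at the
pooled residual df). A small floor ($10^{-5}$ of the median variance)
guards the log scale against numerically zero variances. Each comparison
is fitted independently as a two-group contrast rather than through one
joint multi-condition model; with unbalanced missingness a joint model's
residual pooling would differ, but pairwise fitting keeps every
comparison's df bookkeeping transparent.

**Rank products.** For each replicate pair, ratios are ranked among the
features observed in that pair (rank 1 = most extreme, once per
direction), and the normalized ranks are multiplied across the feature's
observed pairs ($k_{\mathrm{eff}}$ of them). Under the null the normalized
rank product behaves like a product of $k_{\mathrm{eff}}$ independent
uniforms, so the one-sided p-value is the upper Gamma($k_{\mathrm{eff}}$,
1) tail of $-\log \rho$; an exact dynamic enumeration of the discrete rank
null is kept in the test suite and agrees within $2/n$. Two-sidedness is
$\min(1, 2\min(p_{up}, p_{down}))$, making thresholds comparable with the
other tests. Unpaired designs are handled by averaging the paired p-values
over 100 random replicate pairings; missing ratios shrink
$k_{\mathrm{eff}}$ rather than being imputed.

**Permutation test.** The effect statistic is
$u = |\bar b - \bar a| / \sqrt{s_a^2 + s_b^2} \cdot n$ (unpaired; paired
uses the pair differences), with $n$ the number of non-missing values, so
sparse features are penalized through the multiplier. Because the
randomization null needs resolution, conditions with fewer than 7
replicates are augmented with pseudo-replicate columns drawn with
replacement from the pool of all observed values of the compared columns
(a column-set-wide pool, drawn independently per cell; the original
columns are untouched). Each feature's observed $u$ is compared with 1000
randomizations -- random re-partitions of its pooled observed values
(unpaired) or random sign flips of its pair differences (paired) -- and
the p-value is the exceedance fraction with add-one pseudo-counts,
$(\#\{u^{(r)} \ge u^{(i)}\} + 1)/(n_{rand} + 1)$, which lies in
$[1/(n_{rand}+1), 1]$ without capping. Ties count as exceedances, and the
multiplier $n$ is held fixed across randomizations (it models evidence
quantity, which relabeling does not change). The statistic is symmetric in
the two groups, so the implementation canonicalizes the condition order
and relabeled comparisons give identical p-values under the same seed.
The randomization loop is compiled (Rcpp) and uses R's RNG, so a single
`set.seed()` governs everything.

# Multiple testing and the unified FDR

Per-test corrections follow the character of each p-value distribution:
Benjamini-Hochberg for the discrete tests (Miss, rank products,
permutation) and Storey q-values for the two t-type tests, whose
continuous p-values support estimating the null proportion $\pi_0$ (the
smoother method: $\pi_0(\lambda)$ on $\lambda = 0.05..0.95$, cubic
smoothing spline with 3 df, evaluated at $\lambda = 0.95$; with fewer than
100 p-values or a degenerate estimate it falls back to $\pi_0 = 1$, i.e.
plain BH, with a message).

The unified FDR takes, per feature, the four FDRs from the Miss,
moderated, rank-product and permutation tests, corrects the four-fold
look by Hommel's method (valid under positive dependence; identical to
closed testing with Simes local tests), and reports the minimum. Applying
Hommel to FDRs rather than raw p-values is deliberate: it follows the
published construction of the combined score, and keeps each test's own
correction philosophy intact. The result is bracketed by
$\min_i \mathrm{FDR}_i \le \mathrm{unified} \le 4 \min_i \mathrm{FDR}_i$.

# The simulator

`simulateDataset()` reproduces the benchmark conditions under which these
tests were characterized: $N$ features x $2R$ samples of i.i.d.
Normal(0, 1) log-abundances; a fraction $N_R$ of features is displaced by
$\pm\delta$ (one sign per feature, probability 1/2 each, applied to all
replicate values of the second condition -- a per-cell sign would create
no detectable group difference); then $m\%$ of all cells are removed with
per-column weights $(1 - r(i)/N)^\mu$, where $r(i)$ ranks the column
ascending by abundance. $\mu = 0$ gives missing-completely-at-random;
large $\mu$ concentrates removal on low-abundance values (the top-ranked
value of a column is never removed). The removal quota is global (exactly
$\mathrm{round}(m\% \cdot NR2)$ cells over the matrix) because the
benchmark specifies a global fraction; weighted sampling without
replacement uses exponential keys, which is distributionally identical to
sequential weighted draws but O(n log n). Parameter ranges outside the
benchmark table ($N$ 500-10000, $R$ 3-10, $N_R$ 0-50%, $\delta$ 1-5, $m$
0-50%, $\mu$ 0-100) warn rather than error.

What the simulator does *not* emulate: peptide-level structure,
heteroscedastic or intensity-dependent noise, batch effects, correlated
features, or real acquisition-dependent missingness mechanisms. Passing
the benchmark therefore demonstrates correctness of the statistical
machinery under the stated model, not performance on any particular
instrument's data.

# Validation metrics

`confusion()` counts detections (FDR strictly below the cutoff, matching
the convention "FDR smaller than x") against ground truth; the measured
true FDR is $FP/(FP+TP)$, defined as 0 when nothing is detected so grid
summaries aggregate cleanly. `rocPoints()`/`rocAUC()` sweep the threshold;
`nullCalibration()` runs the simulate-test-correct loop over a pure-noise
grid and reports per-dataset false-positive counts. In our standard runs
(48-combination grid, $R \in \{3,5,7,10\}$, $N \in \{1000, 10000\}$,
$m \in \{0, 20, 50\}\%$, $\mu \in \{0, 10\}$) the Miss test yields at most
one FDR < 0.1 feature per dataset, in roughly 5% of datasets.

Problem sizes used in the shipped checks were chosen to characterize the
methods at desk scale: the null grid uses the 48 parameter combinations
above (the acceptance script runs 4 seeded datasets per combination, 192
in total), and the ground-truth recovery runs use 50 seeded datasets at
$N = 1000$, $R = 5$, $N_R = 5\%$, $\delta = 2$, $m = 20\%$, $\mu = 10$ --
a regime where roughly 40% of regulated features are quantified at most
once in one condition, which is exactly where missingness-aware testing
earns its keep.

# Reproducibility

Every randomized step takes an explicit seed. `runTests()` expands one
seed into fixed per-test sub-seeds (drawn once, in a canonical test
order), so switching one test on or off never changes another's stream.
Identical inputs, settings and seed give byte-identical output files.

# Known limitations

* Two-condition contrasts only; no joint multi-condition linear model.
* The Miss test needs a detectable abundance structure: with tiny
  matrices (hundreds of cells) the quantile grid is coarse and the
  discrete p-values are conservative.
* The Hommel step assumes positive dependence among the four per-test
  FDRs; strongly anti-correlated tests would void its guarantee, but the
  four tests share the same data and effect direction.
* The q-value route needs enough p-values (>= 100) for a stable $\pi_0$;
  below that it silently becomes BH (with a message).
* No imputation is offered anywhere, by design.
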