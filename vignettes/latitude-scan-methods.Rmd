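---
title: "Methods: latitude-driven selection scans with latscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitude-driven selection scans with latscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

latscan implements a two-statistic scan for latitude-driven adaptation:
per-SNP population differentiation (Weir–Cockerham F_ST) crossed with a
per-SNP frequency–latitude cline statistic, followed by an empirical
top-decile double filter and gene-set enrichment of the resulting
latitude-related genes (LRGs). This vignette explains the model, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## The differentiation statistic

For each SNP, over the `r` populations with at least one called
genotype, we compute the mean sample size $\bar n$, the sample-size
correction $n_c$, the weighted mean ancestral-allele frequency
$\bar p$, the among-population frequency variance $s^2$ and the weighted
mean heterozygote proportion $\bar h$, and from them the three
variance components

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p)
      - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right],$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2
      - \frac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \frac{\bar h}{2},$$

with $\theta = a/(a+b+c)$ (Weir & Cockerham 1984). Design points:

* **Missing data.** `r` and the $n_i$ are recomputed per SNP from
  non-missing genotypes; a population with no calls for a SNP is simply
  absent for that SNP. The estimator is defined on observed samples, so
  this is the natural convention.
* **Negative estimates are kept.** The moment estimator can go below
  zero for weakly differentiated SNPs; clamping would distort the
  empirical distribution on which the decile thresholds are computed, so
  we do not clamp.
* **Degenerate sample sizes.** When all $n_i$ are equal, $n_c = \bar n$
  algebraically; we set it so explicitly rather than trusting the
  cancellation, and $\sum n_i^2$ is accumulated from integer counts
  (exact in doubles far beyond realistic panel sizes).
* **Undefined SNPs.** Monomorphic SNPs give $a+b+c = 0$ and are flagged
  rather than scored; so are SNPs observed in fewer than two
  populations. Flagged SNPs are excluded from threshold computation and
  can never be selected.
* **X-linked SNPs** are treated as diploid for all individuals: the data
  model carries no sex information, so male hemizygosity is a documented
  simplification. Autosomes and X are nevertheless scored and
  thresholded separately throughout, which absorbs the distributional
  shift between the classes.

## The cline statistic

For each SNP the Pearson correlation between per-population
ancestral-allele frequency and absolute latitude, weighted by population
sample size ($\mu_w$, $\mathrm{cov}_w$ with $\sum w_i$ denominators;
the correlation is scale-free so the normalisation convention cancels).
The selection statistic is $|r_w|$: the direction of a cline is not of
interest, and both allele relabelling and mirroring latitudes across the
equator leave it unchanged (both are tested properties).

Weights default to the *fixed* population sample sizes
(`weight_mode = "population"`), because weighting exists to stop small
populations from dominating the fit, an attribute of the panel design
rather than of per-SNP callability. `weight_mode = "per_snp"` records
the alternative (per-SNP non-missing counts); with call rates in the
high 90s-percent range the two are practically indistinguishable.

Zero weighted variance in either variable makes the correlation
undefined. We detect constancy *exactly* (the per-SNP range of the
observed values is zero) rather than comparing a floating-point variance
to zero, because a constant vector whose weighted mean is not exactly
representable yields a tiny positive variance and a garbage correlation
of ±1 — precisely the failure the flag exists to prevent. Fewer than
three contributing populations also flags the SNP.

## Filters

* **MAF.** A SNP is removed only when its minor allele frequency is
  below the threshold (default 0.05) in *every* population where it is
  observed. This is the weaker, frequency-preserving reading of
  "MAF < 5% in all populations"; the stricter any-population variant is
  available as `maf_mode = "any"`. With worldwide panels the "all"
  filter removes only globally near-fixed SNPs, consistent with it
  removing under 1% of a typical panel.
* **Gene proximity.** A SNP belongs to a gene iff it lies within
  `window` (default 2,000 bp, both bounds inclusive, 1-based
  coordinates) of the gene's span; multiple assignments are allowed and
  all are kept. Only SNPs with at least one gene survive.
* **Y-linked SNPs** are dropped: there are too few to form a separate
  class with stable empirical deciles.

## Two-step selection and its tie behaviour

The empirical threshold for upper-tail fraction $q$ (default 0.10) over
$N$ finite values is the nearest-order-statistic quantile: the
$\lceil (1-q) N \rceil$-th smallest value. Selection keeps values
*strictly greater* than the threshold. This pairing is deliberate: it
makes tie behaviour deterministic and brute-force checkable, and it
reproduces "top 10%" semantics (1..10 at $q=0.1$ selects exactly {10}).
Other quantile conventions shift thresholds by one order statistic on
tied data; with continuous statistics the difference is immaterial.

Step 2's decile is computed **on the step-1 survivors of the same
chromosome class**, not on all SNPs, so the final selection is
approximately $q^2$ of each class. A class contributes only if it has at
least 10 usable values at each step (otherwise it is skipped with a
warning); the threshold function itself only demands two finite values,
since it is also a general-purpose quantile utility. The LRG set is the
union of gene assignments over selected SNPs, de-duplicated across
classes.

## Enrichment statistics

Overlap tests are exact hypergeometric tests of the 2×2 table
$[[k, n_{list}-k], [n_{LRG}-k, N-n_{list}-n_{LRG}+k]]$ against a fixed
gene universe (default $N = 21{,}463$, the number of distinct RefSeq
gene symbols). Two sidedness conventions are implemented:

* `sided = "two"` (default): the minimum-likelihood rule — the sum of
  the probabilities of all fixed-margin tables whose point probability
  does not exceed the observed one (the convention of `fisher.test`,
  against which it is cross-checked; ties in point probability are
  compared with a $1 + 10^{-7}$ relative tolerance, as is customary,
  so equal-probability tables split by rounding error are included).
* `sided = "greater"`: the upper tail, i.e. pure enrichment. Published
  worked examples of this analysis type match the one-sided convention
  (the four disease-list raw p-values and both vitamin-D overlap
  p-values reproduce at printed precision under `"greater"` but not
  under `"two"`), so the acceptance checks use it and record the match.

Bonferroni adjustment multiplies by the number of lists in the current
batch and caps at 1. Identifier matching is exact, case-sensitive string
comparison; alias resolution is a database service out of scope here, so
lists are first reconciled to the universe and out-of-universe symbols
are dropped with a logged count.

The non-synonymous excess test cross-tabulates selected status against
non-synonymous functional class and reports both the Fisher p and the
excess ratio (non-synonymous fraction among selected over that among the
rest, minus one). The gene-length control is a Mann–Whitney test: U is
computed from ranks (equivalent to all-pairs counting with 0.5 credit
for ties); the two-sided p uses the exact null distribution when the
data are tie-free and $n_1 n_2 \le 10{,}000$, and the tie-corrected
normal approximation with continuity correction otherwise. When every
observation is tied the statistic carries no information and p is
reported as 1.

## The synthetic panel generator

`simulate_panel()` emulates the structure of a worldwide human diversity
panel: by default 51 populations, latitudes uniform on [−35°, 65°],
log-normal sample sizes around 16 diploids (clamped to 5–50, matching
the heterogeneity of real panels whose ~18-per-population average hides
sizes from ~6 to ~46), 5,000 SNPs with ~3% labelled X and ~1% Y, ~0.5%
missing calls, and a tiled gene map sized so that ~35% of SNPs fall
within 2 kb of a gene (the proportion seen when intersecting a
genome-wide SNP chip with RefSeq gene bounds).

* **Neutral SNPs** follow the Balding–Nichols model: a global ancestral
  frequency $p \sim U(0.05, 0.95)$ and per-population frequencies
  $p_i \sim \mathrm{Beta}(p\theta, (1-p)\theta)$ with
  $\theta = (1-F)/F$. This model is chosen because it gives a direct
  generator-F ↔ estimator-F_ST correspondence, which is what makes the
  estimator-recovery check meaningful; it is the generator's only
  distributional assumption. Default `f_drift = 0.10`, the magnitude of
  worldwide human differentiation.
* **Clinal SNPs** have expected frequency logistic in |latitude| —
  clines live on the logit scale so frequencies stay inside (0, 1) —
  with residual Balding–Nichols noise at `f_drift / 5` (a planted signal
  should not also carry full drift noise, or it would be partly a drift
  SNP). The slope parameter `beta` is expressed in *frequency units per
  degree at the cline midpoint*: the logit-scale slope is
  $\beta / (\alpha(1-\alpha))$ with intercept frequency $\alpha$
  (default 0.5). We parameterise on the frequency scale because that is
  the scale on which effect sizes of published clines are reported; at
  the default $\beta = 0.008$/degree a 60-degree span moves a mid-range
  frequency by roughly 0.4, a strong but realistic cline. Cline
  direction is random per SNP.
* **Clustering.** Planted SNPs are positioned inside genes drawn from a
  limited target pool (`n_clinal_genes`, default 50), because selection
  signals concentrate at loci; uniform placement would dilute the
  gene-level signal into hundreds of genes, which is not how adaptive
  variation presents.
* **Planted gene lists** draw a stated fraction of their symbols from
  the clinal genes and the rest uniformly from the gene universe;
  `overlap = 0` yields pure-null lists used for calibration.

Everything is driven by one integer seed and is byte-for-byte
reproducible; all emitted files re-read losslessly through the package's
readers.

What passing the synthetic checks does **not** show about real data: the
generator has no linkage disequilibrium (no haplotype statistic is
implemented, so none is needed), no ascertainment bias in SNP discovery,
no shared demographic history beyond the single-F island model (real
panels have hierarchical covariance among populations, which inflates
the variance of F_ST beyond Balding–Nichols), no sex-aware X dosages,
and latitude enters only through its absolute value. Empirical
thresholds and gene counts from real panels are therefore not
reproduction targets of the synthetic pipeline.

## Problem sizes used in validation

The test suite and acceptance script run the estimator-recovery check on
three panels of 5,000 SNPs × 20 populations × 20 diploids at F = 0.10,
and the end-to-end parameter-recovery check on one panel of 5,000 SNPs ×
25 populations with 10% clinal SNPs at F = 0.05 and β = 0.008/degree,
with 100 null lists for calibration. These sizes give sampling error
comfortably inside the asserted bounds (mean θ within ±0.01; ≥5-fold
planted-SNP enrichment) while keeping a full run in seconds.

## Known limitations

* Exact-match gene symbols only; supplying lists with mixed identifier
  types will silently shrink them at reconciliation (the dropped count
  is logged).
* The pipeline is single-threaded and holds the dosage matrix in
  memory; panels of ~10⁶ SNPs × 10³ individuals fit comfortably, but
  biobank-scale data would need chunked readers.
* No LD pruning, Hardy–Weinberg filtering, haplotype statistics,
  hierarchical population structure corrections, or partial correlations
  controlling for shared ancestry: the scan deliberately mirrors a
  two-statistic empirical-decile design, and its outputs should be read
  as an enrichment device, not as per-SNP significance claims.
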