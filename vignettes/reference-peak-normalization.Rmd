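---
title: "Reference-peak normalization for quantitative differential ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-peak normalization for quantitative differential ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refchip)
```

## The problem

ChIP-seq quantifies relative protein–DNA occupancy within one library, but
comparing occupancy *between* conditions requires placing libraries on a
common scale. The standard analytical normalizations — reads per million in
peaks, per million total or aligned reads — all assume that overall binding
does not change between conditions. For treatments that cause genome-wide
changes (the canonical example being degradation of a transcription factor,
where most binding sites lose signal), that assumption fails in the worst
way: normalization redistributes the lost signal, unchanged sites appear
*induced*, and the estimated fold-changes are systematically wrong.

The remedy implemented here is an experimental internal standard: a set of
**reference peaks known to be unchanged** between conditions. These can come
from a *parallel-factor* pull-down (a second antibody against an unrelated,
unaffected factor such as CTCF, mixed into the same immunoprecipitation) or
from a xenogeneic *spike-in* (foreign chromatin with its own antibody).
Everything downstream — size factors, the normalization coefficient, the
MA-plot correction — is estimated **only** from the reference peaks and then
applied to all peaks.

## The model

Let $k_{ij}$ be the read count in peak $i$ of sample $j$, with samples split
into a control and a treated condition. Counts are modeled as negative
binomial, $k_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mathrm{Var}(k) = \mu + \alpha\mu^2$. A multiplicative efficiency bias
$s^*$ (differences in lysis, immunoprecipitation, recovery) acts on every
treated library and is indistinguishable from biology without a reference.

### Normalization coefficient (through-origin regression)

For each reference peak $i$, let $x_i$ and $y_i$ be the mean raw count over
the control and treated replicates. Unchanged reference peaks satisfy
$\mathbb{E}[y_i] = s^* x_i$, so the through-origin least-squares gradient

$$ m = \frac{\sum_i x_i y_i}{\sum_i x_i^2} $$

estimates $s^*$, and the **normalization coefficient** $c = 1/m$ is the
constant that rescales the treated counts so that a refit gradient equals 1
exactly (an algebraic identity, checked to $10^{-9}$ in the tests;
`normalization_coefficient()`, `apply_coefficient()`). The fit is performed
in linear count space on replicate means: a single multiplicative constant
cannot absorb an intercept, and proportional scaling is exactly what an
efficiency bias produces. A log-space variant (`space = "log"`), which
estimates the median/mean log-ratio instead, is exposed as an option; see
*Known properties and limitations* for when it is preferable.

### Control-derived size factors

`control_size_factors()` estimates per-sample DESeq2-style factors from the
reference-peak submatrix only — either proportional to the reference-peak
column sums (`"sum"`) or as the median of per-peak ratios to the row
geometric mean (`"median_ratio"`, robust to a few changing reference
peaks). Factors are rescaled to geometric mean 1 so both methods and the
library-total baseline are on a common scale; the convention is ours (no
established one exists) and makes factors comparable across methods. The
factors then apply to **all** peaks.

### MA correction by a fit to reference log fold-changes

On an MA plot ($A$ = mean log2 normalized count, $M$ = log2 fold-change),
reference peaks are ground truth for $M = 0$. `lfc_fit_correction()` fits
$M \sim b_0 + b_1 A$ by ordinary least squares over the reference rows and
subtracts the fit from every row, after which the reference rows' corrected
$M$ has mean zero by construction. Whether the original procedure used an
intercept-plus-slope or a constant-only fit is ambiguous ("a linear fit");
both are provided, with intercept-plus-slope the default since an
intensity-dependent trend is common in practice.

### Differential binding test

`differential_pipeline()` excludes the reference peaks from the tested set
(their signal is used for normalization, and at reference sites proximity
effects could contaminate the test), then runs a deliberately simple,
fully specified NB Wald test (`nb_wald_test()`): per peak, the GLM
$\log \mu_{ij} = \beta_0 + \beta_1\,\text{treated}_j + \log s_j$ with known
dispersion, fitted by IRLS (tolerance $10^{-8}$, max 100 iterations,
documented moment fallback on non-convergence), two-sided normal reference
for $z = \hat\beta_1/\mathrm{SE}$, Benjamini–Hochberg adjustment
(`bh_adjust()`, verified against exhaustive step-up). There is no
empirical-Bayes shrinkage, no outlier filtering and no independent
filtering: the contribution under study is the *normalization*, and what
matters in the test is its contract — type-I calibration (empirically
0.03–0.07 at nominal 0.05 on nulls) and power monotonic in the effect size —
both of which are asserted in the test suite.

Dispersions (`estimate_dispersions()`) are method-of-moments on normalized
counts, $\hat\alpha_i = \max\{(v_i - \bar\mu_i)/\bar\mu_i^2,\;
\alpha_{\min}\}$ with $v_i$ the pooled within-condition variance, combined
conservatively with a fitted mean–dispersion trend
$\alpha_{tr}(\mu) = a_0/\mu + a_1$ as $\alpha_i = \max\{\hat\alpha_i,
\alpha_{tr}(\bar\mu_i)\}$. The floor $\alpha_{\min} = 10^{-8}$ follows
common NB-GLM practice. The conservative maximum trades a little power for
robustness of the per-peak MoM estimate at 3 replicates.

## Peak-set operations

* `partition_by_genome()` splits combined-genome peak calls by
  species-prefixed chromosome names (longest prefix wins; unprefixed
  chromosomes fall to the default species).
* `filter_control_peaks()` removes reference peaks within 500 bp of any
  target-factor peak, since overlapping target signal would make them
  condition-dependent. Distance is the **edge-to-edge gap** between
  half-open intervals — the anchor (edges vs summits) is a genuine choice;
  edges are the conservative reading (they remove at least as much as any
  summit-based rule at the same radius) and the radius is configurable.
* `consensus_peaks()` merges bases covered by at least `min_occurrence`
  replicate sets into maximal runs. The per-base definition (rather than
  summit matching) behaves identically for narrow transcription-factor
  peaks and broad histone-mark domains, and is verified against a
  brute-force per-base oracle in the tests.
* `count_reads_in_peaks()` assigns a read to a peak when its strand-aware
  5' end lies in `[start, end)`. The 5'-end rule gives each read at most
  one location, making counts deterministic and independent of peak
  ordering; it is a documented choice (fragment-overlap counting, as some
  pipelines use, gives systematically higher counts at wide peaks).
  `min_mapq` defaults to 15, typical ChIP-seq practice.

## The synthetic-data generator

`generate_experiment()` produces the statistical structure the method
assumes, so every stage is testable without sequencing data:

* reference (control) and spike-in peaks with **no** condition effect —
  their treated means carry only the efficiency bias $s^*$ and NB noise;
* target peaks, a fraction of which receive true effects drawn from a
  unidirectional loss distribution $\log_2\mathrm{FC} = -|N(2, 0.5)|$,
  mirroring the near-global loss regime of a degraded factor;
* per-peak expected counts drawn lognormal with median 100
  (`mean_log = log(100)`) and `mean_sdlog = 0.5`. The spread is our choice:
  a high-confidence, consensus-filtered reference set spans roughly an
  order of magnitude in intensity (95% range about 7-fold here); we chose
  it once on those grounds.
* NB dispersion 0.05, typical of well-replicated ChIP-seq peak counts;
* 3 replicates per condition, matching a realistic parallel-factor design;
* `library_totals` modeled as a constant background (default
  $2\times10^6$) plus the in-peak sum — ChIP libraries are
  background-dominated (often under 5% of reads in peaks), which is exactly
  why library-total normalization cannot see an efficiency bias;
* `competition_mode` reproduces the documented spike-in failure mode of a
  cross-reacting antibody: as target signal collapses, spike-in chromatin
  competes less for antibody, so spike-in treated means rise by
  $1 + \kappa(1 - \text{relative target signal})$. The spike-in channel
  then yields a biased coefficient while the internal-control channel does
  not — the directional property is asserted over 50 simulations.

What the generator does **not** emulate: read-level artifacts (duplicates,
mappability, GC), fragment-length effects, peak-calling uncertainty,
partially changing reference peaks, or biological covariance between
neighboring sites. Passing tests therefore demonstrate correctness of the
estimators under the model's assumptions, not robustness to every failure
mode of real data.

## Numerical choices

* Coordinates are BED-convention 0-based half-open everywhere internally;
  conversion to 1-based closed `GRanges` happens only inside interval
  algebra, eliminating ±1 drift.
* Rounding after coefficient application (`rounding = "nearest_int"`)
  is half-away-from-zero: deterministic and sign-symmetric (banker's
  rounding would make results depend on parity).
* The MA pseudocount defaults to 0.5 and is used for display/MA tables
  only — never inside the NB test.
* All-zero peaks get $\beta = 0$, $p = 1$; when one condition is entirely
  zero the fitted mean is floored at $10^{-8}$, bounding the estimate and
  inflating its SE (conservative).
* Cross-normalization (`cross_normalize()`) uses the **median** of
  per-peak offsets between experiments: matched consensus peaks may contain
  residual true-change outliers, and the median also makes the
  post-condition exact (median offset is 0 after correction).
* Subsampling stability uses one RNG stream per (fraction, repetition)
  derived from the master seed, so results do not depend on evaluation
  order.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run entirely on generated data:
coefficient recovery at 5,000 reference peaks; subsampling stability at
50,000 reference peaks with 100 repetitions of 1% draws; type-I calibration
on 20 null experiments of 2,000 peaks (3 vs 3); the competition failure
mode over 50 seeds at 250 peaks per channel. These sizes were chosen to
match the regimes the method targets while keeping each analysis
reproducible in seconds to minutes on one CPU.

## Known properties and limitations

* **Attenuation bias of the linear-space coefficient.** The through-origin
  estimator regresses on *noisy* control-condition means, an
  errors-in-variables situation: $\mathbb{E}[\hat m] \approx s^* / (1 +
  \sum_i \mathrm{Var}(\bar x_i) / \sum_i \mu_i^2)$, i.e. a relative bias of
  about $\alpha/r + \mathbb{E}\mu / (r\,\mathbb{E}\mu^2)$ with $r$
  replicates. At $\alpha = 0.05$ and $r = 3$ this is about $+1.9\%$ on $c$
  — small next to the biases it removes, but visible in tight parameter-
  recovery checks. It shrinks with more replicates and lower dispersion,
  and the log-space option does not have it (log-ratios are unbiased for
  the offset up to a symmetric Jensen term).
* **Subsampling error floor.** The relative error of a coefficient
  recomputed on $n$ subsampled reference peaks has standard deviation at
  least $\sqrt{2\alpha/(r\,n)}$ from the overdispersion term alone,
  independent of sequencing depth and mean level. At $\alpha = 0.05$,
  $r = 3$, $n = 500$ that is $\approx 0.8\%$ per draw — the stability one
  can observe is bounded by the dispersion of the reference peaks, and
  reference sets with lower technical dispersion will look more stable than
  NB-simulated ones at the same size.
* The method corrects **technical** between-condition bias. It cannot
  separate biological batch effects from treatment, and it relies entirely
  on the reference peaks being unchanged: a treatment that perturbs the
  control factor violates the core assumption and silently biases all
  fold-changes.
* Only two-condition contrasts are supported; the test is Wald-type with a
  normal reference, adequate at the peak counts used here but not exact at
  very small replication.
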