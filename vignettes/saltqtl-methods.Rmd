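---
title: "Methods and model details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and model details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltqtl)
```

`saltqtl` is a simulation and analysis toolkit for dissecting a quantitative
trait — NaCl tolerance — in a biparental haploid yeast cross (a laboratory
strain, "BY", crossed to an industrial strain, "CEN.PK"). This vignette
documents the underlying models, the default parameter values and why they
were chosen, the scope of the simulator, and the numerical decisions that
affect results.

## 1. The genetic model

### Marker maps and meiosis

A marker map (`build_marker_map()`) places `n_markers` biallelic SNV markers
uniformly at random across a karyotype, by default the 16 nuclear chromosomes
of the *S. cerevisiae* reference (12,071,326 bp total,
`yeast_chromosomes()`). Markers are the only positions tracked; every
genotype is a vector of parental origins (0 = BY, 1 = CEN.PK).

Meiosis is simulated per chromosome with a Poisson crossover count and
uniformly placed breakpoints (no interference). The expected number of
crossovers is `length_kb * recomb_rate / 100` with `recomb_rate = 0.35`
cM/kb, the commonly used genome-wide average recombination rate for
*S. cerevisiae*. The crossover core is implemented in C++ (Rcpp) but draws
from R's RNG, so `set.seed()` reproduces whole simulations exactly.

### Crossing plans and selection

A `cross_plan()` is a table of generations: the first is always an F1 of the
two founders; each later generation crosses the phenotypically most extreme
segregant of the previous generation to one of the parents. Under
neutrality, the expected donor (CEN.PK) genome fraction follows the
recurrence

* F1: `f = 1/2`,
* cross to the donor parent: `f -> (f + 1)/2`,
* cross to the recurrent (BY) parent: `f -> f/2`.

`fig_plan_iterative_backcross()` encodes the package's reference plan — an
F1, one cross back to CEN.PK, then five successive backcrosses to BY — for
which the recurrence gives `0.75 / 32 = 0.0234375`, i.e. 2.34% residual donor
genome. `simulate_neutral_donor_fraction()` confirms this by Monte-Carlo
meiosis.

### The trait

Phenotypes are additive over a small set of trait loci
(`trait_model()`). Each BY allele at a locus contributes
`effect * conc_scaling * concentration` to growth, plus Gaussian noise
(`noise_sd = 0.1`). The packaged default architecture
(`default_trait_loci()`) has a major BY-favouring locus on chrIV near 530 kb
(`effect = +1.0` per mol/L NaCl) and a minor CEN.PK-favouring locus on chrIX
near 115 kb (`effect = -0.2`); both are snapped to the nearest map
marker. This two-locus, opposite-sign architecture produces transgressive
segregation and gives the QTL scan one strong and one weak target with
opposite expected frequency shifts. Phenotypes are evaluated on a fixed
concentration grid (0.25–2.5 M in 0.25 steps); selection defaults to 1.5 M
and plate phenotyping examples use 0.75 M.

## 2. Pooled sequencing and the G′ scan

### Pool simulation

`simulate_pools()` contrasts a reference pool (the whole segregant
population) with a selected pool (the top `survival_fraction` of phenotypes
at the selection concentration — truncation selection). Read counts at each
marker are binomial draws of the pool allele frequency at a Poisson-dispersed
depth (`mean_depth = 100` per pool).

Defaults: `n_pop = 10000` segregants and `survival_fraction = 0.01`. The
population size matters: with 1% truncation it leaves ~100 survivors, and the
sampling noise of those ~100 linked genomes — not sequencing depth — sets the
noise floor of the scan. Much smaller populations give strongly correlated
drift along chromosomes that mimics QTL peaks.

### Variant filtering

`filter_variants()` keeps records with combined depth strictly greater than
100 (`min_depth`), quality-by-depth `QD >= 2.0`, and
`MQRankSum >= -5.0`; missing annotations pass. Rejection counts per rule are
attached as an attribute.

### The G statistic and tricube smoothing

At each SNV the 2×2 table of reference/alternative read counts in the two
pools yields the likelihood-ratio statistic
`G = 2 * sum(n * log(n / n_hat))` with the `0 * log(0) = 0` convention; a
zero marginal gives `G = 0`. The smoothed `G'` is the tricube-weighted
average of `G` over a window (`window_bp = 20000`, so half-window
`D = 10` kb; weight `(1 - (d/D)^3)^3`), computed per chromosome — windows
never span chromosome ends. This follows the G′ method of Magwene, Willis
and Kelly (2011, *PLoS Comput Biol* 7:e1002255) as popularized by the
`QTLseqr` package.

### Null model and interval calling

The null distribution of `G'` is estimated by fitting a lognormal to
`log(G')` after two-sided Hampel trimming (median ± 5.2·MAD, the
conventional Hampel constant); `meanlog` and `sdlog` are the median and MAD
of the trimmed values. Upper-tail p-values follow; the discovery threshold
is `-log10(p) >= 1.30`, i.e. `p <= 0.05`.

Because a calibrated per-SNP threshold of 0.05 flags ~5% of null SNPs
genome-wide — dozens of spurious intervals on a 2,000-marker scan — interval
calling additionally requires a Benjamini–Hochberg `q <= 0.05`
(`max_q`; set to `NULL` to disable). This mirrors `QTLseqr`'s FDR-based
calling. Significant SNPs closer than `merge_gap_bp = 20000` are merged into
one interval; intervals are reported with 1-based inclusive coordinates (and
0-based half-open in BED exports) and sorted by peak significance.

## 3. Plate phenotyping

Relative NaCl tolerance normalizes a test strain against reference-strain
colonies spotted on the same plates:

`tolerance = (test_nacl / mean(ref_nacl)) / (test_ypd / mean(ref_ypd))`.

The double ratio cancels multiplicative plate effects; a strain matching the
reference means on both plates has tolerance exactly 1. Tolerances are
binned into right-closed classes of width 0.05 (`assign_class()`), so the
reference value 1.0 falls in class 20. Growth-curve parameters
(`fit_growth_params()`) are nonparametric: the maximum rate is the largest
smoothed finite-difference slope, lag is the tangent-intercept time against
a baseline from the first three points, and AUC is trapezoidal. On an exact
logistic curve the maximum rate approaches `r * K / 4`.

## 4. Modality calls

`classify_modality()` compares one- and two-component Gaussian mixtures fit
by a hand-written EM (10 restarts for k = 2, quantile plus random
initialization; variance floor `1e-6 * var(x)`; convergence when the
log-likelihood changes by less than `1e-8`; monotone likelihood ascent is
asserted each iteration). Model choice uses
`BIC = (3k - 1) * log(n) - 2 * logLik`; "bimodal" requires
`BIC(k=1) - BIC(k=2) > 100`, a deliberately strict margin so that only
clearly separated phenotype modes — e.g. a still-segregating major locus —
are called bimodal. The decision is invariant under affine rescaling of the
data (the fitted parameters are equivariant up to the EM stopping
tolerance).

## 5. Allele association

`longest_homorepeat()` scans protein sequences for the longest run of a
residue (default asparagine, N); runs are strictly consecutive, `X` or `*`
breaks a run (with a warning), and letters outside the amino-acid alphabet
are errors. `classify_asg1()` labels alleles CENPK-like when the Asn run is
at least 20, else BY-like. `stratified_compare()` compares growth between
the two classes separately within each ENA transporter dose stratum using
Welch's two-sample t-test, reporting the percent difference of means; strata
with fewer than two strains in either class are skipped and flagged.

## 6. Scope and limitations of the generator

The simulator is intentionally small and transparent rather than realistic:

* no crossover interference, no gene conversion, no mutation, no aneuploidy
  or mitochondrial inheritance;
* markers are biallelic and error-free apart from binomial read sampling;
  there is no reference bias or mapping artifact model (QD and MQRankSum
  annotations are synthetic draws used only to exercise the filters);
* the trait is strictly additive on a fixed concentration grid — no
  epistasis, dominance (all individuals are haploid), or
  genotype-environment interaction beyond linear concentration scaling;
* selection is deterministic truncation on the phenotype, not a survival
  probability model.

Default problem sizes are desk-scale: 2,000 markers, populations of 10^4,
and depth 100 run end-to-end in seconds on one CPU. All stochastic
functions take explicit seeds and are exactly reproducible.

## 7. Numerical conventions

* `0 * log(0) = 0` throughout the G statistic; `G` is clamped at 0 against
  rounding.
* Tricube smoothing uses `findInterval()` window lookups and is exactly
  equal to the brute-force double loop (tested to 1e-12).
* p-values are clamped into `(.Machine$double.xmin, 1]`.
* `assign_class()` uses `ceiling(value / 0.05 - 1e-9)` so grid values such
  as exactly 1.0 land in the closed upper bin despite floating-point
  representation.
* Null estimation requires at least 50 positive `G'` values and errors on a
  zero MAD instead of returning a degenerate fit.
* Output tables are written with 6 significant digits; reading them back is
  lossless for all semantic comparisons at that precision.
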