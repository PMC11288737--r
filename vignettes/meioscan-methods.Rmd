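---
title: "Models and methods behind meioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscan)
```

meioscan analyses meiotic-sterility phenotypes in plants with large
karyotypes (its defaults are for soybean, 20 homolog pairs). This
vignette explains the statistical models, the simulator that generates
the package's synthetic data, the numerical choices, and the known
limitations.

## Chiasma counts and crossover interference

Crossovers (COs) form through two pathways: Class I COs are
interference-sensitive — a CO suppresses further COs nearby, producing
*under-dispersed* per-cell counts (variance < mean) — while Class II COs
are interference-insensitive and accumulate independently, producing
Poisson counts. A cytologist scores chiasmata at diakinesis/metaphase I
from bivalent morphology: a ring bivalent (chiasmata in both arms)
counts 2, a rod (one arm) 1, a univalent pair 0. This convention is the
standard one and is consistent with a wild-type soybean cell of ~18
rings + 2 rods ≈ 38–39 chiasmata; `chiasmata_from_morphology()`
implements it, and `chiasma_dataset()` cross-validates morphology
against directly supplied counts.

The diagnostic statistic is the dispersion index, `var/mean` of the
per-cell counts (1 under Poisson, ≪ 1 under interference), and the
formal test compares the empirical count distribution against
Poisson(λ̂), λ̂ the sample mean.

### Discrete Kolmogorov–Smirnov test

`ks_poisson_test()` evaluates

\[ D = \sup_k |F_n(k) - F_{\hat\lambda}(k)| \]

over the integers \(k = 0, \dots, \max(x)\). Because both CDFs are step
functions jumping at integers, this range attains the supremum over the
whole support; a test asserts agreement with a brute-force sweep on
every small dataset.

Two p-values are offered:

* **bootstrap** (default, B = 2000): resample `n` counts from
  Poisson(λ̂), re-estimate λ per resample (unless λ was supplied fixed),
  recompute D\*, and report `p = (1 + #{D* ≥ D})/(B + 1)`. This is the
  correct recipe for a discrete null with an estimated parameter; the
  classical asymptotic theory assumes a continuous, fully specified
  null and is conservative here. The test suite verifies calibration
  directly: over 1,000 datasets truly drawn from Poisson(8.41) at
  n = 158, the rejection rate at α = 0.01 falls within three
  Monte-Carlo standard errors of 1%.
* **asymptotic**: the Kolmogorov limiting distribution evaluated at
  √n·D, retained because published comparisons of this kind typically
  used it. Both modes agree on the direction of every conclusion in the
  test suite.

α defaults to 0.01, the level conventionally quoted for this
comparison. The bootstrap p is bounded below by 1/(B+1); all-zero count
vectors are degenerate and return p = 1 with a warning.

The two study regimes behave as theory predicts: the mutant-like
Poisson regime (mean 8.41, n = 158) is not rejected, while the
wild-type regime (mean 38.50, SD 1.41, n = 123; dispersion ≈ 0.05) is
rejected in essentially every seeded replicate — the package's tests
measure a rejection rate above 99% over 200 simulated wild-type
datasets.

## Forward meiosis simulator

`simulate_dataset()` composes, per homolog pair and independently
across pairs and cells:

* **Class I**: when enabled, one obligate CO (wild-type soybean forms
  20/20 bivalents without fail, so the obligate CO is the default) plus
  an "extra" count with mean `class1_mean_extra` and a dispersion
  parameter `class1_dispersion` ∈ (0, 1] defined as variance/mean of
  the total per-pair Class I count.
* **Class II**: Poisson(`class2_rate`) per pair.

A pair with ≥ 1 CO is a bivalent; achiasmate pairs yield two univalents
each. Every univalent pair segregates in a balanced way with
probability 1/2 independently (`daughter_balanced` is true when all
pairs balance — exactly the \((1/2)^u\) model, and the simulator serves
as its Monte-Carlo oracle in the tests). Each univalent lags at
anaphase I with probability `p_lag` (default 0.5; only qualitative
realism is claimed for lagging counts).

### Generating under-dispersed integer counts

Interference is modelled at the count level, not the spatial level: the
evidence the package is designed around is purely count-distributional,
so a spatial gamma-renewal placement model would add parameters nothing
in the data constrains. To draw integers with an exact target mean m
and variance v ≤ m we use a mixture of Poisson(m) (weight w) and the
two-point lattice distribution on {⌊m⌋, ⌊m⌋+1} with mean m (weight
1 − w). Both components share the mean, so choosing
`w = (v − f(1−f))/(m − f(1−f))` with f = frac(m) matches the variance
exactly. Two limits matter: v = m gives w = 1, i.e. *exactly* Poisson —
so setting `class1_dispersion = 1` with no obligate CO makes the two
pathways statistically indistinguishable, a property the tests check —
and v = f(1−f) gives the most regular integer draw the lattice allows
(requests below that bound error out; a simple rounded-normal
"quantised" draw cannot reach small variances at small means at all,
which is why the mixture construction is used). Requests with v > m
(over-dispersion) are rejected: interference only removes variance.

### Presets

* `wildtype`: obligate CO, `class1_mean_extra = 0.925`,
  `class1_dispersion = 1.41²/38.50 ≈ 0.0516`, no Class II. Per-cell
  chiasma counts then have mean 20 × 1.925 = 38.50 and SD 1.41; every
  cell has 20 bivalents ("20 ± 0.00").
* `mlh1_mutant`: Class I off, `class2_rate = 8.41/20 = 0.4205`, making
  the per-cell total exactly Poisson(8.41).

`calibrate_class2_rate()` inverts the pure-Class II model:
λ₂ = value/n_pairs for a chiasma-mean target, λ₂ = −ln(1 − value/n_pairs)
for a bivalent-mean target. Note a deliberate, documented tension: a
per-pair Poisson model with mean chiasmata 8.41 predicts
20(1 − e^(−0.4205)) ≈ 6.87 mean bivalents, while 6.40 is the observed
figure the fertility algebra uses. The two cannot both be matched by
any per-pair-i.i.d. Poisson model (residual COs would have to cluster
on fewer pairs); the simulator exposes dispersion as a free parameter
rather than resolving what the data cannot decide, and the presets
match the chiasma mean.

## Fertility under random univalent segregation

`p_balanced(u) = (1/2)^u` is the probability that u independently
segregating univalent pairs all balance. For observed bivalent counts,
`expected_balanced_from_bivalents()` offers:

* **plugin** (default): u = n_pairs − mean(bivalents) plugged into the
  exponent — the convention used for headline numbers (6.40 bivalents →
  u = 13.6 → 0.008%);
* **distributional**: the exact expectation E[2^−(n_pairs−B)] over the
  per-cell counts, which by Jensen's inequality is always ≥ the plugin
  value (strictly, unless counts are constant). The gap is small for
  tight distributions but the exact form is the defensible one when
  per-cell data exist.

Percentages are rounded half-up at the printed precision
(`round_half_up()`), so 2^−10 → 0.10% and 2^−5 → 3.13%; base R's
banker's rounding would give 3.12.

## Segregation-ratio test

`chi_square_ratio_test()` is the uncorrected Pearson χ² goodness of fit
to a stated ratio (default 3:1), with df = classes − 1 and a
`consistent` verdict against the α = 0.05 critical value (3.84 for
df = 1). The Yates continuity correction is available via
`correct = TRUE` but off by default: for counts such as 142:39 the
uncorrected statistic (1.15) is the conventionally reported one, the
corrected value being ≈ 0.97. `fold_change()` is a plain ratio reported
to two decimals; note that for a pair like 8.79%/2.25% it reports 3.91,
and any differently printed figure for that pair cannot be reproduced
as either the ratio (3.91) or the relative increase (2.91).

## BSA-seq scan

The SNP index of a variant is `AD_alt/(AD_ref + AD_alt)`; sites with
total depth < `min_depth` (default 8, chosen to stabilise indices at
~30× coverage) are treated as missing rather than erroneous.
`window_scan()` averages usable indices in windows of `window_bp`
(default 200 kb) advancing by `step_bp` (default 50 kb), anchored at
position 0 on each chromosome so window boundaries do not depend on
which variants are present; only full-size windows are emitted, and a
window needs ≥ `min_variants` (default 10) usable variants for a mean.
VCF positions are 1-based; windows, regions and BED output are 0-based
half-open throughout. `call_candidate_regions()` keeps windows with
mean index strictly > 0.9 and merges overlapping or book-ended ones
(via IRanges), reporting each region's peak window mean. A Δ(SNP-index)
against a control pool is deliberately not the default: the scan is
defined on the selected bulk alone, and a control subtraction can be
performed by the caller on two window tables.

### Synthetic bulk

`simulate_bsa_bulk()` builds the bulk plant by plant: every selected
plant is homozygous mutant at the planted locus, so all 2 × 39 = 78
founder gametes carry the mutant allele there. Each gamete's haplotype
is extended outward from the locus as a Markov recombination walk: the
carrier state flips between adjacent markers with the Haldane fraction
of the interval, `r = (1 − e^(−2d))/2` (d in Morgans, from bp through
`kb_per_cM`, default 400 kb/cM). Haldane fractions compose, so the
marginal carrier probability at distance d is exactly 1 − r(d) while
neighbouring markers remain linked as on a real chromosome — which is
what makes window profiles realistically smooth. Read support is
Poisson(`mean_depth`, default 30) with Binomial allele sampling.
Defaults: one 10-Mb carrier chromosome with the locus at 5 Mb, markers
every 400 bp (~2.5 variants/kb, the density divergent-parent
resequencing typically yields), and a 2-Mb unlinked control chromosome
whose founder states start from a fair coin.

What the generator emulates: finite-bulk sampling noise (39 plants),
depth noise, physical linkage, and the monotone decay of the expected
index from 1 at the locus to 0.5 unlinked (`expected_snp_index()` gives
the analytic curve). What it does not: inter-marker ascertainment,
mapping/calling artefacts, repeat-dense regions with suppressed
recombination, and any interference in the gametes' recombination walk
(Haldane is interference-free by construction). Consequently a passing
pipeline demonstrates the *computation* recovers a planted locus under
idealised sequencing, not that real soybean data are this clean.

With these defaults the top-scoring candidate region contained the
planted locus in 50/50 seeded replicates in the test suite's run. The
above-0.9 domain occasionally (roughly a fifth of seeds) sheds a small
secondary shoulder region: near the index-0.9 crossing the bulk
frequency is a 1/78-step staircase, and a sub-threshold run longer than
the 150-kb overlap tolerance splits the domain. The package reports
such shoulders honestly rather than bridging gaps with a smoothing
heuristic the calling rule does not define; callers who want one region
can take the peak-index region, as the tests do.

## Problem sizes and runtime choices

The test suite sizes its simulations to be decisive yet quick: 1,000
replicates (B = 2000) for KS calibration, 200 for KS power, 10⁵ cells
per u for the segregation oracle, 10⁴ cells for preset consistency, and
50 replicates for locus recovery. These sizes give Monte-Carlo standard
errors several times smaller than the effects being checked.

## Known limitations

* Chiasma counts are taken as scored; no image analysis, and no
  per-chromosome chiasma localisation.
* The KS test addresses only the Poisson family; other count nulls
  (e.g. negative binomial for over-dispersion) are out of scope.
* The fertility model ignores selection among aneuploid spores and
  possible male/female differences (heterochiasmy).
* The BSA scan consumes a VCF; alignment, variant calling and gene
  annotation within candidate intervals are upstream/downstream of this
  package.
* The kb↔cM scaling is configuration: real local recombination rates
  vary by an order of magnitude along a chromosome.
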