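---
title: "Simulating rare-variant architectures and evaluating gene-based tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rare-variant architectures and evaluating gene-based tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarepower)
```

## The problem

Sequencing studies of complex disease routinely test genes, rather than
single variants, for association: when causal alleles are rare (MAF < 1%),
the power to detect any one of them individually is negligible, and the
field has produced a zoo of aggregate tests — burden-style collapsing and
weighted-sum statistics, variance-component (dispersion) statistics, and
adaptive combinations of the two. How much power these tests actually have
depends on the *locus architecture*: the joint distribution of causal-variant
frequencies, effect sizes, and effect directions. rarepower provides a
controlled laboratory for that question. It simulates sequence variation at
gene-sized loci with realistic frequency spectra and haplotype structure,
plants causal effects under explicit architectures, draws case-control
cohorts under a liability-threshold disease model, runs a battery of twelve
association tests implemented from scratch behind one interface, and
aggregates the results into power, calibration, concordance, and composite-
test summaries.

## Reference panel simulation

All genotype data descend from a phased haplotype panel over a synthetic
contig (0-based coordinates internally; 1-based in VCF output).

**Base panel.** `simulate_base_panel()` grows haplotypes sequentially with a
Li-and-Stephens-style copying process: each new haplotype is a mosaic of the
haplotypes simulated before it, switching templates along the chromosome at
a per-bp intensity `rho` (default 5e-4, giving visible linkage-disequilibrium
decay across a few kb) and acquiring copy errors at a per-site probability
`0.5 * theta / (theta + k)` that shrinks as the panel of size `k` grows —
the classic product-of-approximate-conditionals construction, under which
the site frequency spectrum comes out rare-skewed as for neutral variation.
The default `theta = 0.01` per bp was calibrated (once, against the target
below) to give exome-like variant density at gene scale. The base panel
stands in for a real phased reference panel of 379 European individuals;
real panels can be imported from VCF or IMPUTE2 `.hap/.legend` files
instead.

**Expansion.** Large case-control simulations need a panel far bigger than
any single-ancestry public resource, so `expand_panel()` augments the base
panel to 12,514 individuals by iteratively appending mosaic haplotypes (with
no phenotypic effects), 300 individuals per iteration, each copying from all
haplotypes present at the start of its iteration. During expansion the
mutation parameter is `theta = 0.08`, chosen to recreate the singleton
excess observed in large exome-sequencing studies: copy errors introduce new
rare alleles at existing sites, and brand-new singleton columns arise at
exonic positions not yet segregating, at `0.25 * theta` new sites per added
haplotype. How a copying model's mutation parameter should split between
copy errors and genuinely new sites is not identifiable from published
descriptions of such simulators; the 1:0.25-per-haplotype split used here is
a package design choice, fixed during the one-time density calibration. The
expansion switch intensity is deliberately small (`rho = 1e-5`) so that
haplotype structure is inherited rather than eroded; the package tests hold
mean pairwise r² for common (MAF > 5%) site pairs within ±0.05 of the base
panel in every distance bin.

**Spectrum calibration.** Raw expansion overshoots rare-variant density, so
`thin_to_sfs()` removes whole variant columns by seeded rejection sampling
until the retained spectrum matches a target — never editing genotypes
within retained columns, which is what preserves LD while correcting
density. The bundled `sfs_target_exome()` is a singleton-dominated,
qualitatively exome-like spectrum (46% singletons, decaying through MAC and
MAF classes to 3.5% common) with a default density of 60 variants/kb in the
full 12,514-individual panel. It is parameterised, not copied from any
published table; its one quantitative anchor is the calibration target that
a 1.5 kb coding locus sampled at 3,000 individuals segregates a **median of
~38 exonic MAF < 1% variants**. Thinning to a target that would require
*adding* variants to a bin raises an explicit infeasibility error. The
per-bin deviation tolerance between realized and target proportions is
0.02 by default.

## Genetic architectures

`architecture_model()` bundles six canonical regimes relating causal-variant
frequency to per-allele relative risk (RR): strong, moderate, or absent
inverse coupling (ar1-ar3, causal variants across the full spectrum),
rare-only variants under strong or moderate coupling (ar4, ar5), and a
bidirectional regime (ar6) that uses the moderate map with a 50/50 mixture
of risk and protective draws, protective effects entering as inverted
relative risks. Maps are weight grids over (MAF bin × RR bin); the bundled
ones come from a parametric family in which the median log RR in a MAF bin
scales as `(maf / 0.01)^-c` — `c` = 0.30, 0.15, 0 for strong, moderate,
absent coupling — around a median RR of 1.65 at MAF 1%, log-normal spread
0.3, capped at RR 4.5 so that penetrances stay feasible under a
common-disease prevalence. These are qualitative stand-ins for
architecture distributions that, in the literature, come from forward
population-genetic simulation; such simulation is out of scope here, and a
user with an externally derived map can supply it as a TSV grid.

## Liability-threshold effect sizes

The disease model is a dichotomised standard-normal liability with
prevalence `K` (default 0.08, a type-2-diabetes-like common trait). For a
variant with risk-allele frequency `q` and per-allele RR under additive
dosage coding (het RR, hom 2RR−1), `variance_explained()` solves the
baseline penetrance so the population risk equals `K`, maps each genotype's
penetrance `f_g` to a liability mean shift `qnorm(1-K) − qnorm(1−f_g)`, and
returns the between-genotype variance as a fraction of total liability
variance, `Vg / (1 + Vg)`. The `Vg/(1+Vg)` normalisation (rather than raw
`Vg`) is the package's documented convention; at the effect sizes simulated
here the two differ by under 1%, and users can recover raw `Vg` as
`ve / (1 - ve)`. A protective minor allele (RR < 1) is recoded as a risk
effect of the major allele — algebraically equivalent, and it keeps all
penetrances positive for any RR > 0, which the naive hom coding `2RR − 1`
would not. The implementation is validated against a brute-force
numerical-integration oracle to 1e-6 relative error.

`sample_locus_effects()` assembles a causal set to a target locus VE
(grid: 0.5%, 1%, 2%): pick an exonic panel variant at random, draw its RR
from the architecture map, accumulate VE; keep adding while below
`0.95 × target`, remove one introduced effect uniformly at random when above
`1.05 × target`, and accept inside the window — restarting from scratch if
acceptance would need more than 35 causal variants (a cap mirroring the
practical limits of haplotype-resampling simulators; at 3K scale it binds
rarely). Infeasible draws (penetrance outside (0,1)) are rejected and
redrawn; an oscillation guard (10,000 steps) and a restart budget (default
1,000) bound the loop. Locus VE is the sum of per-variant VE — an explicit
independence assumption between causal variants at a locus.

## Cohort ascertainment

`sample_cohort()` forms diploid individuals by drawing two mosaic-perturbed
haplotypes from the panel (template copy, rare switches, copy errors; no new
sites), computes each individual's disease probability
`f0 × Π_v m_v(g_v)` — multiplicative across causal variants, additive in
dosage within a variant, with `f0` solved so the expected risk over panel
genotype frequencies equals the prevalence — and assigns case/control status
by a Bernoulli draw, retaining individuals until the two quotas (default
1500/1500) fill. This prevalence-constrained rejection sampling is a
deliberate re-derivation of the haplotype-segment over-sampling that
reshuffling simulators use for ascertainment: under the stated risk model
the target distributions coincide, and the rejection form is directly
verifiable (the package tests check that the population-average risk solves
back to `K` and that null cohorts have exchangeable case/control counts).
Risks are never clipped; a genotype whose computed risk reaches 1 raises an
error rather than silently distorting the model. When the causal set is
empty the sampler short-circuits to direct labelling, which is exactly
equivalent because status is then independent of genotype. Genotypes are
emitted unphased (dosages 0/1/2) since every test in the battery is
genotype-based; monomorphic columns are dropped. `causal_fraction_filter()`
implements neutral-variation dilution: it keeps every causal site and
removes neutral rare sites uniformly at random until causal:total among
rare sites equals 0.25, 0.5, 0.75, or 1.

## The test battery

Twelve tests run behind one interface on the identically filtered dataset
(`run_test_battery()`); variant inclusion uses the sample MAF from the
combined case+control sample with a *strict* `<` threshold (default 1%; a
site exactly at the threshold is excluded — the convention follows the
usual "variants with MAF < 1%" phrasing of rare-variant analyses).

* **CMC** — collapse to a carrier indicator, likelihood-ratio test of
  logistic regression. Degenerate indicators (all or no carriers) return
  p = 1 by convention rather than erroring.
* **BURDEN / UNIQ** — summary-count statistics (total rare alleles in
  cases; case-unique allele observations), one-sided permutation p.
* **FRQWGT** — inverse-frequency weights `1/sqrt(n q (1-q))` with `q`
  estimated from controls (add-one smoothing), statistic = summed case
  score; weights are recomputed inside every permutation because the label
  exchange moves individuals between weight-estimation pools.
* **WILCOX-WSS** — one-sided rank-sum on the same weighted scores, normal
  approximation with tie correction.
* **VT** — burden z-statistic maximised over every distinct observed MAF
  threshold, thresholds re-scanned per permutation.
* **KBAC** — individuals grouped by multi-site rare-genotype pattern, each
  pattern weighted by the hypergeometric-tail probability of its observed
  case enrichment, statistic = weighted case-count sum, one-sided
  permutation p.
* **C-ALPHA** — per-site `(y_i − n_i p0)² − n_i p0 (1−p0)` summed,
  permutation p (bidirectionally sensitive).
* **SKAT** — variance-component score statistic with Beta(1,25)-density
  MAF weights (the de facto default of kernel association testing; the
  battery exposes flat weights as an option), p-value from the
  mixture-of-chi-square null via Imhof's characteristic-function
  inversion with a Liu moment-matching fallback below the inversion's
  ~1e-6 noise floor.
* **SKAT-O** — `Q_rho = (1−rho) Q_SKAT + rho Q_burden` over the grid
  `{0, 0.1², ..., 0.5², 1}`; the grid-minimum p is calibrated by
  one-dimensional numeric integration over the shared burden-direction
  component, with a Bonferroni cap over the grid as a guard.
* **MiST** — stage 1: score test of the weighted-burden aggregate;
  stage 2: variance-component test of per-variant heterogeneity with the
  burden score as a null-model covariate (making the stage p-values
  independent under the null); combined by Fisher's method (chi-square,
  4 df). No covariates beyond the burden: the simulations include none.
* **SINGLE-FISHER** — two-sided Fisher's exact test on the per-site allele
  2×2 table, no MAF filter, locus summary = minimum p.

**Permutation machinery.** All permutation tests share one engine: when
`choose(n, n_case)` is small (≤ 50,000) the null is enumerated exactly over
all label assignments — this is what lets the suite check the permutation
tests against independent exhaustive oracles on ≤ 10-individual fixtures —
and otherwise labels are resampled with the add-one correction
`p = (1 + #{T* ≥ T}) / (B + 1)`, which keeps p-values valid (super-uniform)
under the null. Permutations start at 1,000 and escalate tenfold, up to a
configurable ceiling (default 1e6), while fewer than 10 exceedances have
been seen — the resolution needed for thresholds like 2.5e-6 at feasible
cost. Battery runs seed each test's permutation stream independently from
one master seed, so battery rows and single-test calls reproduce exactly.

## Evaluation

`estimate_power()` reports, per design cell, the fraction of replicates
with p strictly below each threshold (a tie at alpha is a non-detection)
with exact binomial confidence intervals; the full study design uses 100
replicates per gene. `fpr_corrected_threshold()` replaces the nominal alpha
with the empirical null quantile per test, so differently conservative
tests can be compared at a matched false-positive rate.
`concordance()` computes R² of −log10 p between tests over loci where both
report p ≤ 0.1. `combined_power()` decomposes detections into
single-variant-only, gene-based-only, both, and neither at the conventional
thresholds (5e-8 single-variant genome-wide, 2.5e-6 gene-based exome-wide =
0.05/20,000). `forward_select_composite()` greedily builds a composite test:
starting from one member, repeatedly add the candidate contributing the
most novel signals — loci where the candidate's p is below alpha and beats
the best included p by a multiplicative margin (100, 10, or 1) — and score
the composite by its per-locus minimum p, with an FPR adjustment computed
on that min-p statistic's empirical null (the min-p rule inflates the
false-positive rate, so unadjusted composite gains largely vanish after
adjustment). Novel-signal counting is per locus-replicate.
`power_single_variant()` provides the analytic (normal-approximation
allelic test) and Monte-Carlo (Fisher's exact) single-variant power used
for the combined analyses.

## Numerical choices and degenerate inputs

Tolerances and conventions that matter: panel MAF is stored folded
(`min(f, 1-f)`) with allele code 1 fixed to the base panel's minor allele;
the SFS-thinning feasibility check errors rather than silently adding mass;
the Imhof integral is clamped to [1e-14, 1] and hands off to Liu below
1e-6; a non-positive quadratic-form cutoff returns p = 1 analytically
(a positive mixture always exceeds it); eigenvalues below 1e-10 of the
largest are treated as null space; constant phenotypes raise an explicit
zero-residual-variance error; "remove one introduced effect" in the VE loop
is a uniform draw over the current causal set; and all stochastic functions
take a `seed` argument that sets a local RNG state and restores the
caller's, with pipeline stages deriving child seeds through a documented
linear splitting scheme.

## What the generator does and does not emulate

The synthetic panel reproduces three features the evaluation depends on: a
rare-dominated exome-like site frequency spectrum calibrated at the ~38
rare-variants-per-locus level, LD decay with distance that survives panel
expansion, and a mutation process that keeps injecting very rare variation
as sample size grows. It does **not** emulate demographic history, multiple
populations or admixture, gene-length variation (loci are fixed at an
average coding length of 1.5 kb), non-coding architecture, sequencing or
genotyping error, relatedness, or covariate structure. Consequently,
passing tests show that the statistical machinery behaves correctly under
the stated generative model — they do not certify power numbers for any
real study, whose architecture parameters are unknown and whose artefacts
(stratification, batch effects, call-rate filters) are outside this model.
Power values under the bundled parametric maps are qualitative: orderings
and trends (monotonicity in effect size, sample size, causal fraction;
collapse of one-sided tests under bidirectional effects) transfer; absolute
percentages do not.

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks over many shallow ones,
at sizes chosen for CI-scale runs: exhaustive permutation oracles on 8- and
10-individual fixtures (70 and 252 labelings); liability-VE oracle
agreement on a 16-point grid; panel pipelines at the full 12,514-individual
scale for one 1.5 kb and one 1 kb locus, shared across tests; null
calibration of all twelve tests over 1,000 cohorts of 250 cases / 250
controls with permutations capped at 1,000; Monte-Carlo single-variant
power at 1e4 Fisher simulations; and reduced-replicate (order 10-60)
power-trend checks with interval-aware comparisons. The acceptance script
regenerates the headline panel calibration from scratch at 100 loci.

## Limitations

Beyond the generative-model caveats above: the SKAT-O grid-search
calibration and MiST stage combination rely on asymptotic approximations
that can be conservative in small samples with very sparse genotypes;
permutation p-values are resolution-limited by the adaptive ceiling;
the bundled architecture maps are not fitted to any dataset; and the
composite-test FPR adjustment conditions on the selected member set rather
than re-running selection under the null, matching how such composites are
used in practice but slightly understating selection noise.
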