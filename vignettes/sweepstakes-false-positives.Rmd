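---
title: "Sweepstakes reproduction and the type I error of bottleneck tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweepstakes reproduction and the type I error of bottleneck tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Genetic bottleneck tests — the M-ratio, the heterozygosity-excess test,
Tajima's *D*, and model-based size-change estimators — all take a stable
Wright–Fisher population as their null: random mating with essentially
Poisson-distributed family sizes, i.e. a variance in reproductive success
(*V~k~*) of 2 at a mean of 2 offspring per mating. Many high-fecundity
organisms violate this badly: under *sweepstakes reproductive success* a few
"winner" families produce most of the next generation, and the ratio of
effective to census size collapses as

$$N_e/N_c \approx \frac{4}{V_k + 2}.$$

`srsfpr` asks, by forward simulation of demographically *stable* populations:
how often do these tests wrongly report a bottleneck when *V~k~* is large?
The false positive rate (FPR) of each test is estimated on an
*N~e~* × *V~k~* grid of stable populations.

## The simulator

The population model is individual-based, diploid, with constant census size
and non-overlapping generations:

* **Census size.** For a target effective size *N~e~* and variance *V~k~*,
  the simulated census is `census_size(ne, vk)` = *N~e~*(*V~k~*+2)/4, rounded
  and forced even.
* **Mating.** Each generation, all individuals are shuffled into disjoint
  monogamous pairs; each pair draws one family size. If the census is not
  filled after a round of pairs, individuals are re-paired and mating
  continues; the last family is truncated so the offspring generation has
  exactly *N~c~* members. Disjoint pairing makes the per-parent offspring
  variance equal to the family-size variance — the quantity that enters the
  *N~e~*/*N~c~* relationship above. (An alternative scheme that redraws a
  random pair per mating event *with replacement* inflates the per-parent
  variance to roughly *V~k~*+4, which at *V~k~* = 2 would halve the realized
  effective size and visibly depress equilibrium heterozygosity; we therefore
  do not use it.)
* **Family sizes.** Poisson(2) for *V~k~* = 2. For *V~k~* > 2,
  `floor(Gamma(shape, scale))`: a long-right-tailed discrete distribution
  (approximately negative binomial) in which most pairs produce no offspring.
  The two gamma parameters are free and are calibrated by nested bisection so
  that the *floored* distribution has mean 2 and variance *V~k~* exactly;
  moments are computed by analytic summation of the discretised mass function
  (truncated where the tail mass drops below 1e-12), so calibration is
  deterministic and is verified to better than 0.1%.
* **Markers.** 15 unlinked microsatellites under the strict stepwise
  mutation model (±1 repeat, rate μ = 5×10⁻⁴ per locus per generation);
  optionally range-constrained loci where mutation reflects inside a window
  of 5 adjacent repeat states (EST-like markers); or a single 500-bp
  sequence under the infinite-sites model at μ = 10⁻⁷ per site.
* **Sampling.** 50 individuals drawn uniformly without replacement.

The inner generation loop (pairing, inheritance, stepwise mutation) is
compiled (Rcpp) and draws from R's RNG stream, so every replicate is
reproducible from a single integer seed; a master seed deterministically
spawns per-cell and per-replicate seeds.

### Initialization and burn-in

Populations must be at mutation–drift equilibrium before sampling; the
expected equilibrium heterozygosity of the stepwise model is the closed form
$H_e = 1 - 1/\sqrt{1+2\theta}$ with $\theta = 4N_e\mu$. Burn-in runs for
*N~e~* generations, recording population-level K, H~e~ and F~is~ every few
generations; convergence is declared when the least-squares slope of the
second half of the H~e~ trajectory is below 5×10⁻⁵ per generation.

*N~e~* generations are only sufficient if the starting state is already
close to equilibrium. Relaxation of heterozygosity takes roughly
$1/(1/2N_e + 4\mu)$ generations, longer than the burn-in itself, and — more
insidiously — a start with *excess* alleles sheds them over ≫ *N~e~*
generations, leaving bottleneck-like gaps in the allele range (we measured
mean M-ratios of ~0.82 after an *N~e~*-generation burn-in from a wide
10-state start, where the equilibrium value is ~1.0). The default
initialization therefore starts *at* the equilibrium marginals and slightly
*below* in allele count, letting mutation build the spectrum upward:

* number of adjacent initial repeat states: $m = \max(1,\;
  \mathrm{round}(1 + 2\sqrt{\theta}))$, which tracks the equilibrium sample
  allele count of the stepwise model (≈1.5 at θ = 0.1, ≈3 at θ = 1);
* symmetric Dirichlet concentration chosen so the expected initial
  homozygosity equals the equilibrium value: $(\alpha+1)/(m\alpha+1) =
  1/\sqrt{1+2\theta}$.

Both are overridable (`n_init_alleles`, `dirichlet_conc`). Sequence loci
start monomorphic and burn in for 10 *N~e~* generations instead.

### Infinite sites on a finite locus

A 500-bp locus cannot literally host one mutation per site over thousands of
generations (tens of thousands of mutation events occur during burn-in). A
physical site is therefore *occupied* only while its derived allele
segregates: sites whose derived allele is lost are freed, and sites fixed
for the derived allele are re-polarised to ancestral and freed. Every
segregating site in any sample still traces back to exactly one mutation
origin — the property the infinite-sites statistics rely on — and the
simulation stops with an error in the (never observed at these mutation
rates) event that more than 500 sites segregate simultaneously.

## The four tests

All tests take the stable Wright–Fisher population (*V~k~* = 2) as their
null, at significance level α = 0.05 throughout.

* **M-ratio, fixed threshold** (`m_ratio_ft_test`): call a bottleneck when
  the dataset-mean ratio of occupied to possible allelic states
  (`k/(range+1)`, monomorphic loci counted as 1) falls strictly below the
  0.68 rule of thumb.
* **M-ratio, simulated critical value** (`m_ratio_sim_test`): the null
  distribution of the dataset-mean M is rebuilt from 1000 Kingman-coalescent
  stepwise-mutation datasets at the *true* θ = 4*N~e~*μ of the generating
  process; the critical value is the empirical 5% order statistic (lower
  tail, no interpolation). Because the null depends only on (θ, sample size,
  locus count), it is computed once per grid cell and shared across
  replicates.
* **Heterozygosity excess** (`het_excess_test`): per polymorphic locus,
  Nei's unbiased H~e~ is compared with the equilibrium heterozygosity
  expected for the *observed allele count* under the Wright–Fisher stepwise
  model. That expectation is estimated by accept–reject coalescent
  simulation over a logarithmic θ grid (0.05–50), conditioning on the allele
  count, with at least 500 accepted loci; values are memoised by (sample
  size, allele count) under a key-derived seed, so the memo table is a fixed
  deterministic object. A one-tailed Wilcoxon signed-rank test (exact for
  small samples without ties, normal approximation with continuity
  correction otherwise; zero differences dropped) calls significance. Fewer
  than 4 polymorphic loci: the test is flagged not applicable.
* **Tajima's D** (`tajima_test`): D computed from S and π with the standard
  constants; S = 0 samples are excluded (D undefined). The one-tailed
  p-value (positive side — the decline signal) comes from 1000 constant-size
  infinite-sites coalescent simulations at θ̂ = π, the estimate an
  empiricist would use; simulated S = 0 datasets contribute D = 0.

## The experiment grid

`grid_spec()` defaults define the reference study design: *N~e~* ∈ {50, 500, 2500,
5000} × *V~k~* ∈ {2, 40, 400, 2000}, 100 replicates per cell. Since every
simulated population is demographically stable, the fraction of replicates
in which a test fires *is* its type I error; `run_cell()`/`run_grid()`
aggregate per-cell means, SDs and FPRs with Clopper–Pearson 95% intervals
into a single results table. Cells with *N~e~* ∈ {2500, 5000}
and *V~k~* ∈ {400, 2000} (census up to 2.5 million forward-simulated
individuals) are excluded from the default profile and run only under
`full = TRUE`.

Problem sizes used in the shipped checks: 30 replicates per examined cell
(100 for the *N~e~* = 50 reference cell), 1000 coalescent simulations per
null distribution, ≥500 accepted simulations per equilibrium-heterozygosity
value. At these sizes a full acceptance run is a matter of minutes on one
core.

## What the simulator reproduces — and what it does not

The *V~k~* = 2 grid cells reproduce the classical expectations in detail:
mean sample H~e~ matches $1-1/\sqrt{1+2\theta}$ (≈0.09 at *N~e~* = 50,
≈0.42 at *N~e~* = 500), allele counts and M-ratios match the coalescent
null (K ≈ 3.1, M ≈ 1.0 at θ = 1), F~is~ ≈ 0, and all four tests hold false
positive rates at or below their nominal level.

For *V~k~* ≫ 2 with the census tied to *N~e~* by *N~c~* =
*N~e~*(*V~k~*+2)/4, this model makes a sharp — and perhaps surprising —
prediction: the sample genealogy stays close to the Kingman coalescent of
size *N~e~*, and the bottleneck tests keep near-nominal error rates. The
reason is a cancellation. The probability that two sampled individuals are
full sibs is (*V~k~*+4)/(2*N~c~*); substituting the census formula gives
≈ 2/*N~e~*, *independent of V~k~*. As *V~k~* grows at fixed *N~e~*, the
census grows exactly fast enough that winner families remain a vanishing
fraction of the population: per-replicate we observe mean F~is~ ≈ 0, M ≈
0.93–0.98 and K near the coalescent value at (*N~e~* = 500, *V~k~* = 400),
with a mild *excess* of rare variants (the direction multiple-merger
coalescent theory predicts). Sweepstakes genealogy distortions — sib-heavy
samples, strongly negative F~is~, gap-ridden allele ranges, positive
Tajima's D, inflated FPRs — require family sizes that are an appreciable
fraction of the census, i.e. *V~k~* of order *N~c~*; they emerge in this
simulator when the census is small relative to the family-size tail (for
example *N~e~* ≤ 50 at *V~k~* ≥ 400), not along the constant-*N~e~* grid
diagonal. Published analyses that report large type I errors on that
diagonal are, in this model's terms, operating in the
family-comparable-to-census regime. Users studying sweepstakes effects
should therefore choose (*V~k~*, *N~c~*) jointly — the package places no
constraint on simulating, say, census 500 with *V~k~* = 400 directly by
passing the appropriate *N~e~*.

Other known limitations: hermaphroditic monogamous-pair mating only (no
separate sexes, selfing, migration, selection, age structure, or linked
loci); strict single-step mutation (no two-phase model); the final family
of a generation is truncated at the census boundary, which at small census
sizes compresses the realized family-size variance below the calibrated
target (logged per generation as realized variance if needed for audit);
the equilibrium-heterozygosity conditioning follows the
allele-count-matching convention and a strict SMM, where the classical
program offers further mutation-model options.

## Numerical choices

* Calibration tolerance 1% relative on both moments; root searches to
  1e-10–1e-12.
* Mutation counts per generation are Poisson(μ × gene copies), the standard
  approximation to per-copy Bernoulli at these rates; a repeat count
  mutating below 1 reflects (1 → 2), as do steps at the constrained-window
  edges.
* The empirical 5% critical value uses `sort(null)[floor(0.05 n)]` — the
  conservative lower order statistic, no interpolation.
* Wilcoxon p-values: exact when < 50 informative differences and no ties,
  else normal approximation with continuity correction; ties arise only
  through the shared H~eq~ of equal-allele-count loci and are handled by the
  approximation.
* Monomorphic loci: M = 1 (no evidence of gaps), excluded from F~is~
  (undefined), counted in %P's denominator.
* S = 0 sequence replicates are excluded from mean-D and FPR denominators;
  the per-cell report carries the exclusion count.
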