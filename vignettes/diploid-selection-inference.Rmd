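---
title: "Inferring general diploid selection from time-series allele counts"
author: "selhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring general diploid selection from time-series allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selhmm)
```

## The model

selhmm estimates how natural selection acted on a biallelic locus from
allele counts sampled at several points in time, as produced by
ancient-DNA time series or evolve-and-resequence experiments.  Genotypes
`AA`, `Aa`, `aa` have relative fitness `1 + s2`, `1 + s1`, `1`; the pair
`(s1, s2)` is *general diploid selection*.  Familiar one-parameter modes
are lines through this plane: additive (`s1 = s2/2`), dominant
(`s1 = s2`), recessive (`s1 = 0`) and heterozygote difference (`s2 = 0`;
`s1 > 0` is complete overdominance, `s1 < 0` complete underdominance).

The population allele frequency `Y_t` follows the discrete Wright-Fisher
model: given `Y_t = p`, the next generation is `Binomial(2 Ne, p') / (2
Ne)` with

    p' = p + p (1 - p) (s1 (1 - 2 p) + s2 p),

which we approximate by a normal distribution with mean `p'` and variance
`p (1 - p) / (2 Ne)`.  The data at sampling time `t` are `a_t` focal
alleles among `n_t` sampled haplotypes, modelled as `Binomial(n_t, Y_t)`.
Because `Y_t` is unobserved, inference runs in a hidden Markov model
whose states discretize the frequency into `M` values.

### Why Chebychev nodes

The hidden states are the Chebychev nodes `g_i = 1/2 - 1/2 cos(pi i /
(M-1))` rather than an equidistant grid.  Near the boundaries the
Wright-Fisher variance `g (1 - g) / (2 Ne)` collapses, and an equidistant
grid has intervals much wider than the transition kernel, so the
discretized chain badly misrepresents the dynamics exactly where
trajectories under strong selection spend their time; estimates are then
biased downward.  The Chebychev spacing shrinks like the distance to the
boundary, keeping the kernel-to-interval ratio roughly stable.
Equidistant grids remain available (`freq_grid(M, "equidistant")`) for
comparison only.

Transition probabilities integrate the normal kernel exactly over each
interval (differences of normal CDFs at the interval midpoints).  The
outermost intervals stretch to plus/minus infinity, so mass drifting
outside `[0, 1]` is absorbed by the boundary states and each row sums to
one without renormalization.  The states at 0 and 1 have zero variance
and are exact absorbing point masses, matching the diffusion's absorbing
boundaries.

## The hybrid EM estimator

If the whole frequency path were observed, the Gaussian-increment path
likelihood would be maximized in closed form by a 2x2 linear system (the
objective is exactly quadratic in `(s1, s2)`).  With partial observations
we alternate:

* **E-step** — scaled forward-backward under the discretized HMM, giving
  the data log-likelihood and the posterior expectations
  `E[H_t]`, `E[F_t H_t]`, `E[F_t^2 H_t]`, `E[F_1]`, `E[F_T]` and
  `E[F_t (F_{t+1} - F_t)]` (with `H = F (1 - F)`) summed over
  generations.  Joint posteriors are never materialized; only these sums
  are accumulated, so memory stays `O(T M)`.
* **M-step** — the closed-form maximizer of the *continuous* expected
  complete-data likelihood, plugged with the discrete expectations.  For
  a one-parameter mode, the quadratic objective restricted to the
  constraint line `a s1 = b s2` is maximized in closed form along the
  direction `(b, a)`; this is the Lagrange-multiplier solution with the
  multiplier eliminated analytically.

This hybrid (discrete expectations, continuous maximization) is not an
exact EM, so the likelihood is not guaranteed to ascend monotonically.
The loop therefore runs at least `min_iter` iterations (default 5) and
reports the maximum log-likelihood observed together with the parameters
that attained it.  The minimum-iteration rule also matters statistically:
without it, many near-neutral fits stop immediately at `s = 0` and report
a likelihood ratio of exactly one, distorting the p-value distribution
near 1.

The initial frequency distribution is either fixed or estimated as a
beta distribution, discretized over the same intervals as the
transitions (boundary intervals receive the tail mass).  Its update
maximizes the posterior-weighted log-mass objective numerically on the
log scale, with shapes bounded in `[1e-3, 1e3]`; this part *is* an exact
EM update, so the implementation keeps the previous values whenever the
optimizer fails to improve the objective.  Unbounded, the update can
drift toward ever-more-concentrated shapes on flat likelihood plateaus,
which is why the bound exists.

### Defaults and their rationale

| parameter | default | why |
|---|---|---|
| `M` (hidden states) | 500 | estimates are stable for 250-2000 states and biased below 250; 500 balances accuracy and cost.  Desk-scale simulations in the tests use 250, inside the stable range. |
| convergence tolerance | `1e-3` on the log-likelihood | small against the chi-square(1) scale of the tests built on these likelihoods |
| `min_iter` | 5 | p-value calibration near 1 (see above) |
| `max_iter` | 500 | termination guarantee; non-convergence is flagged, not discarded |
| `(s1, s2)` start | `(0, 0)` | neutral start makes mode fits comparable and nested |
| `(alpha, beta)` start | `(1, 1)` | uniform-density initial distribution |

## Testing for selection and classifying its mode

For one mode, `D = 2 (ll_s - ll_0)` is referred to a chi-square(1)
distribution (`lrt_pvalue()`); both fits treat the initial-distribution
parameters as nuisance parameters and estimate them.  A single temporal
series is far from the asymptotic regime of Wilks' theorem, so the
chi-square reference is an approximation that the simulation tests in
this package verify empirically.

Because the hybrid M-step carries a discretization error of its own, an
EM fit of an alternative mode can stall within numerical noise of — or
even below — the neutral fit, even though the alternative nests the
null and its true maximum cannot be lower.  Left alone, such fits
produce a spurious point mass of likelihood-ratio statistics at exactly
zero (p-values at exactly 1).  `fit_all_modes()` therefore treats these
cases as optimizer failures and resolves them in two stages: refit the
mode warm-started at the neutral fit's nuisance estimates, and if the
statistic is still below its resolution floor, maximize the exact
discrete-HMM likelihood directly over the single constrained coefficient
(a 1-D profile search with the initial distribution held at the neutral
estimates).  Both stages only tighten the lower bound on the
alternative's maximum; they affect only the near-neutral regime (raw
statistics below `restart_margin = 0.01`, i.e. p-values above ~0.92) and
leave significant loci untouched.

With the mode unknown, `delta = -2 (ll_0 - max_m ll_m)` over the four
one-parameter modes is also referred to chi-square(1)
(`classify_mode()`): the chi-square(2) reference is offered for
comparison but is poorly calibrated, and the unconstrained two-parameter
fit has visibly higher variance than the constrained modes, which is why
classification relies on the one-parameter fits and documentation steers
users to them first.  Because the best of four correlated statistics
replaces one well-calibrated statistic, delta p-values are mildly
anti-conservative in the tail — on neutral data at the 5% level the
rejection rate is nearer 6-7% than 5%.  When neutrality is rejected the
label is the argmax mode; heterozygote difference splits into
overdominant/underdominant by the sign of `s1`.  Exact likelihood ties
are resolved in the fixed order additive, dominant, recessive,
heterozygote difference and flagged — the procedure must be
deterministic.

## Effective population size

`estimate_ne()` sums *conditioned* neutral log-likelihoods over loci on a
grid of candidate `Ne` values and interpolates with a natural cubic
spline on `(log Ne, ll)`.  The conditioning divides each locus's
likelihood by the probability of seeing at least one polymorphic sample;
without it the composite surface is nearly flat in the large-`Ne`
direction.  During `Ne` estimation the initial distribution is fixed to
the uniform density, never co-estimated — co-estimation lets the initial
distribution absorb drift-scale information and biases the surface.  The
default grid (9 log-spaced values spanning a factor of 8 either side of
a guess) and the spline interpolant are this package's choices; results
report the grid used.  Expect a slight upward bias with small variance
for batches of a thousand or more loci.

## The simulator

`simulate_dataset()` emulates the designs used to validate this class of
methods: discrete Wright-Fisher trajectories under the five modes,
binomial sampling of `n_t` haplotypes at the chosen generations
(equidistant or arbitrary), per-haplotype missingness thinning, and
rejection conditioning evaluated *on the samples*: directional modes
require the focal allele not fixed in the first sample and not lost in
the last; overdominance requires segregation in the last sample;
underdominance in the first.  Initial frequencies are fixed, drawn from
the neutral standing-variation spectrum (`1/i` weights on `i / (2 Ne)`),
or supplied per replicate — the latter is the hook for matching an
empirical initial-frequency distribution from real data.  With a
time-varying `Ne` schedule, the first generation's size defines the
standing-variation support.  Defaults (`Ne = 10^4`, `T = 251`, `p0 =
0.25`, 11 equidistant sampling times of 50 haploids) are the reference
simulation-study conditions for this problem.

What the simulator does *not* emulate: linkage between loci (replicates
are independent), sequencing error, reference bias and SNP-array
ascertainment.  Passing tests therefore demonstrate correctness of the
inference machinery under the model's own assumptions, not robustness to
every artifact of real ancient-DNA data; for a specific dataset, a
data-matched simulation (same sampling scheme, missingness and initial
frequencies) is the recommended check.

## Genome-scan layer

Per-SNP filters require data at two or more timepoints, strictly more
than a configurable total of samples (default 50), and pooled minor
allele frequency strictly above 0.05.  Raw p-values are aggregated over
overlapping windows of 50 loci (the focal SNP, 25 upstream, 24
downstream; windows truncated at chromosome ends are rescaled by
`50/size` so sums stay comparable — a documented convention, flagged in
output).  The negative log-p sums are referred to a scaled chi-square
distribution fit genome-wide by moment matching (`c = Var / 2 Mean`,
`f = 2 Mean^2 / Var`), the canonical estimator for combining dependent
p-values this way.  Benjamini-Hochberg thresholds on raw and
post-processed p-values then define candidate regions: contiguous runs
of post-significant loci containing at least one raw-significant locus.
An isolated significant SNP whose neighbours are quiet is diluted by its
window and calls no region — the behaviour that suppresses genotyping
artifacts, at the price of also suppressing any true signal confined to
a single SNP.  Lead-SNP confidence intervals come from a parametric
bootstrap (refit simulated replicates matching the fitted model, correct
by the mean bootstrap bias — an additive correction, chosen here — and
take the 2.5%/97.5% quantiles).

## Numerical choices

* Scaled forward-backward (normalized forward variables, accumulated log
  scale factors) rather than log-space recursions; generations without
  data use an implicit all-ones emission.
* The transition matrix is effectively banded — the drift kernel spans a
  handful of grid intervals — and the C++ kernel restricts products to
  the detected band (entries below 1e-15 are outside it), which is what
  makes desk-scale resimulation studies feasible.
* Impossible data (zero total likelihood) reports `-Inf`, never an
  exception; degenerate M-step systems (e.g. monomorphic data) fall back
  to the current estimate and are flagged.
* Negative likelihood-ratio statistics from numerical noise in nested
  fits are clamped to zero.

## Problem sizes used in the package's own validation

The test suite and the acceptance script rerun the method's validation
experiments at desk scale, chosen so the full suite completes on one
CPU: neutral-calibration and single-alternative calibration use 2,000
replicates at `M = 250` (inside the stable 250-2,000 range for the EM);
parameter recovery uses 200 replicates per mode and selection strength;
`Ne` recovery uses 10 batches of 2,000 loci at `M = 500` — the
composite-likelihood surface is more sensitive to the discretization
than the selection estimates are, and coarser grids bias the recovered
size upward by ~20%.  These sizes give binomial/KS noise comfortably
inside the bands stated alongside each experiment.

## Known limitations

* Constant selection coefficients; time-varying selection is out of
  scope.
* Time-varying `Ne` is handled heuristically (simulate with the true
  schedule, analyze with a constant composite-likelihood estimate); a
  severe bottleneck or exponential growth would need re-validation.
* The chi-square(1) null for delta is an approximation; scenario-specific
  parametric-bootstrap calibration is a documented extension point, not
  implemented.
* Single-locus likelihoods only; linked-site information enters solely
  through the windowed p-value aggregation.
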