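---
title: "Local ancestry inference with admixpaint: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local ancestry inference with admixpaint: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixpaint)
```

## The problem

An admixed genome is a mosaic: recombination breaks the chromosomes
inherited from distinct ancestral populations into ever-shorter tracts, so
that `g` generations after a mixing event the tract lengths are
approximately exponential with rate `g − 1` per Morgan. admixpaint infers,
at fine scale, which latent ancestral mixing group each segment of an
admixed genome descends from — **without** assuming that any reference
panel is a direct surrogate for a mixing group. The relationship between
panels and latent ancestries is itself learned from the data.

## The two-layer copying model

Each target haplotype is modelled as an imperfect mosaic copy of donor
haplotypes (a Li-and-Stephens copying process) with a second, slower hidden
layer: the local ancestry. The hidden state at a position is the pair
(ancestry `a`, donor haplotype `h` in panel `p`).

*Grid.* All computation happens on an even grid in genetic distance
(default 60 gridpoints/cM); markers are mapped to their nearest gridpoint
(midpoint ties go to the lower index, for determinism) and recombination is
approximated as occurring only between gridpoints. A gridpoint may carry 0,
1 or many markers, so runtime scales with genetic span, not marker count.
Chromosomes are independent: each restarts the chain from its initial
distribution.

*Transitions.* Between successive gridpoints, for target individual `n`:

* ancestry switch `b -> a`: probability `Pi[b,a](n)`, after which the donor
  is redrawn from panel `p` with probability `mu[p,a] / N_p`;
* no ancestry switch: with probability `(1 − Pi[a,·](n)) · rho` the donor is
  redrawn the same way (background, within-ancestry recombination); with the
  complementary probability the state is unchanged. An explicit
  same-ancestry switch `Pi[a,a]` is allowed and counts toward the row sum
  `Pi[a,·]`, the only reading under which kernel rows sum exactly to 1.

The `A x A` matrices `Pi(n)` carry everything the model knows about the
event (time and proportions) and are per-individual by default; `mu`, `rho`
and the miscopy rate `theta` are shared across the admixed sample. The
columns of `mu` sum to 1; `mu` is the learned panel-ancestry relationship
and is the method's key output besides the local ancestry itself.

*Emissions.* A marker emits `1 − theta` if the copied donor allele matches
the target allele and `theta` otherwise; a gridpoint emits the product over
its markers, and an empty gridpoint emits 1 — which is also how missing
genotypes are handled (fewer observations, never imputation).

*Initial distribution.* The chain starts with ancestry weights proportional
to the total switch mass into each ancestry (column sums of `Pi`,
normalised — a stationary-flavoured proxy for the mixing proportions) and
donor weights `mu[p,a] / N_p` within ancestry. An all-zero `Pi` falls back
to uniform weights with a warning.

## Inference

The forward–backward pass is implemented in C++ with per-gridpoint
rescaling; the factorised kernel (switch destinations do not depend on the
source state) gives an `O(G · (A² + A·K))` sweep. Parameters are fitted by
Baum–Welch EM with closed-form tied updates. Because the same-ancestry
kernel entries mix two mechanisms (explicit `Pi[a,a]` switches and
`rho`-switches), the expected event counts are accumulated by decomposing
each pairwise transition posterior into its generative components; `theta`
and `rho` then update as pooled expected fractions, `mu` columns as
normalised expected donor-choice arrivals (arrivals via either mechanism —
both select the donor through `mu` — so that the M-step maximises the full
expected complete-data likelihood), and `Pi[b,a]` as expected `b -> a`
arrivals over expected intervals with source ancestry `b`. Row sums of
`Pi` cannot exceed 1 by construction. `theta` is floored at 1e-6 and `rho`
clamped to [1e-6, 1 − 1e-6].

Note that `Pi[a,a]` and `rho` are only weakly identified from each other
(their observable consequences are identical up to pooling across
ancestries and targets); this does not affect local ancestry or dating,
which never read the `Pi` diagonal.

*Initialisation and restarts.* `mu` starts at `1/P` per entry with ±10%
multiplicative jitter (columns renormalised): the jitter is mandatory,
since exactly symmetric columns make the ancestries exchangeable. `Pi`
starts at `alpha0 · lambda0 · w` (uniform `alpha0`, `lambda0` = 30 switches
per Morgan, `w` the grid step in Morgans), `rho` at 0.05, `theta` at 0.01.
The likelihood surface is multi-modal in the jitter — noticeably so for
three or more ancestries — so the pipeline screens several jittered starts
(default 5) with a short EM burn-in and commits to the best by
log-likelihood.

*Algorithm loop.* Rounds of: donor **thinning** (an ancestry-unaware
single-layer painting ranks donors per gridpoint; the top `K = 100` per
target individual — summed over its two haplotypes, ties to the lower donor
index — are retained); **rephasing** (below); and 10 EM iterations. The
loop ends at a round that accepts no phase flips, or at the round cap
(default 5). A final EM then runs to convergence (relative log-likelihood
change below 1e-5 by default), followed by one E-step for posteriors,
coancestry dating, and drift summaries.

The two-layer engine consumes the per-chromosome *union* of the
per-gridpoint retained donor sets: with per-gridpoint state spaces the
factorised kernel would no longer be a proper transition kernel (rows must
sum over a fixed donor set). The per-gridpoint sets are still what the
thinning module computes and reports, and on reference pools up to a few
hundred donors the union's log-likelihood loss versus the full pool is
below 0.1%.

*Phase hunting.* Statistical phasing errors in the targets can masquerade
as ancestry switches. For each diploid we compute, from one
forward–backward pass per haplotype, the marginal change in log-likelihood
if the two haplotypes' alleles at a single gridpoint were swapped — the
posterior-weighted emission swap
`gain(g) = Σ_s [γ1(g,s) − γ2(g,s)] · [ℓ(y2|s) − ℓ(y1|s)]`.
Runs of positive gain form candidate intervals; the highest-gain,
non-overlapping intervals (≥ 0.1 cM apart) are flipped, the model is refit,
and the pass is reverted if the total log-likelihood did not increase.
Passes repeat while the likelihood improves (cap 25). Flips swap alleles
between the haplotypes only, so diploid genotypes are invariant; there is
no cap on flips per region. The exact marginal-gain estimator is a design
choice validated by recovery simulations (≥ 70% of injected 2%-rate flips
corrected within five passes) rather than by an external formula.

## Dating admixture by coancestry curves

For ancestries `a, b`, the relative probability of observing `a` at one
position and `b` at genetic distance `d` away, relative to the genome-wide
average, follows `P(a,b,d) = δ_ab · exp(−d·λ_ab) + τ_ab` for a single
pulse, with `d` in Morgans so `λ_ab` reads as generations since admixture
and `τ_ab ≈ 1`. Curves are computed per chromosome by FFT
cross-correlation, pooled as ratio-of-pooled-sums across targets and
chromosomes (stable for rare ancestries; per-target curves are also kept
for display), and fitted by nonlinear least squares initialised from the
crude closed form (`τ = 1`, `δ = P(d_min) − τ`, `λ` from the mid-curve
point); a coarse `λ`-grid fallback with linear solves covers degenerate
initialisations. Lags below `d_min = 0.5` cM are excluded — the model's own
smoothing inflates tiny-lag ratios — and the default range ends at 30 cM.

By default the curves are built from the **maximal-a-posteriori ancestry
calls** rather than the posterior probabilities (`curve_source` option).
The two coincide as posteriors approach certainty; at the sparse marker
densities used in this package's synthetic studies (10 markers per cM) the
posterior track is visibly smoothed by the HMM, which attenuates the
fitted decay rate by 15–20%, while the hard-call track recovers simulated
rates essentially unbiased. Hard assignment is the same rule used to build
the partial ancestral genomes for the Fst summaries.

Dates are reported per pair and averaged (`flexible`), or fitted with one
shared rate (`single`). Uncertainty comes from a chromosome bootstrap
(resample chromosomes with replacement, recompute pooled curves from cached
per-chromosome statistics, refit). Orderings of multiway events are called
from bootstrap ±2 SE interval overlaps and reported as narrative text only:
pairwise decays cannot always identify a history uniquely, and no formal
multi-pulse test is attempted.

## Drift and accuracy summaries

*Partial ancestral genomes.* Each gridpoint of each target haplotype is
assigned to its maximal-posterior ancestry (ties to the lowest index); the
alleles at its markers join that ancestry's reconstructed genome, whose
haploid sample size therefore varies along the genome.

*Fst.* A Weir–Cockerham-style ratio-of-averages estimator built from
per-site terms `a, b, c, d` (numerator and denominator summed over sites
before the ratio), chosen for robustness to per-site sample-size variation;
sites with combined haploid size below 3 are skipped. When an inferred
minor ancestry has essentially no mass (< 0.5% genome-wide, flagged with a
warning) the between-ancestry Fst is meaningless — the estimator breaks
down with an empty group.

*Rst.* The panel-averaged relative squared difference of the two
ancestries' Fst to each panel, in [0, 2]; negative Fst cells are floored at
0, and panels with zero Fst to both ancestries contribute 0 with a warning.
Low Rst flags panels that cannot differentiate the mixing groups — the main
reason for low accuracy in practice.

*Expected r².* The expected squared correlation between inferred and
(unobserved) true local ancestry, computed from the posterior alone by
treating truth as Bernoulli draws from it (haploid) or sums of two
independent Bernoullis (diploid dosage); diploid pooling concatenates
gridpoints across individuals. Because it assumes the model fit is
accurate, it overestimates the realised r² under misspecification — the
simulations here reproduce that overconfidence direction.

*Selection scan.* Mean diploid ancestry dosage per gridpoint across
individuals, a z-score against the genome-wide mean using the
across-individual SE, and a −log10 two-sided normal p, explicitly labelled
exploratory (no genome-wide significance theory is attached). Any 1 Mb
physical window with fewer than 10 markers is masked.

## The synthetic test bed

The generator provides the controlled conditions every recovery test runs
under:

* **Populations** diverge from a common ancestor by pure drift:
  ancestral site frequencies Uniform(0.05, 0.95) (avoiding monomorphic
  sites; any still monomorphic after simulation are dropped with a
  message), per-population frequencies Balding–Nichols
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` with drift `F = 0.1` by default.
* **Within-population LD** comes from emitting each panel haplotype as a
  Li-and-Stephens mosaic of a founder pool (Poisson founder switches, 30
  per Morgan; per-site copy error 0.002). The founder pool defaults to 10
  haplotypes per population, matching the effective number of founder
  lineages implied by the drift coefficient (on the order of `1/F`); panels
  default to 30 haplotypes each, the size of a typical population sample.
* **Admixed diploids** carry ancestry tracts broken at Poisson rate
  `lambda_gen` per Morgan, with the ancestry *redrawn i.i.d. from `alpha`*
  at every breakpoint (including same-ancestry redraws), so the
  pairwise-ancestry autocorrelation decays at exactly `lambda_gen` —
  making date-recovery tests sharp. The classical `g − 1` statement is
  exposed through `generations_to_rate()`. Within a tract, alleles are
  copied verbatim from a random source-population haplotype, re-chosen at
  each breakpoint and at 30 per Morgan within tracts. Source haplotypes
  are split off *before* inference panels (`split_panels()`), so the true
  mixing haplotypes are never available as donors.
* **Truth** is recorded as exact tract tables (convertible to per-gridpoint
  indicator matrices), and optional phase scrambling swaps the two
  haplotypes at Bernoulli-selected gridpoints with full bookkeeping of the
  effective (heterozygous) flips.
* The default map is uniform at 1 cM/Mb; the HMM operates in genetic
  distance, so map realism is irrelevant to every test here.

What the generator does **not** emulate: coalescent gene trees, mutation
beyond copy error, gene conversion, crossover interference, background
selection, or the internal admixture of real reference panels. Passing
recovery tests on this test bed therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not performance on
real cohorts.

## Study sizes and numerical choices

The bundled studies run at desk scale: two chromosomes of 100 cM, 2,000
markers (10 per cM) for two-way studies, 10 admixed diploids, panels of 30
haplotypes. Three-way accuracy studies use 6,000 markers (30 per cM, still
several-fold sparser than a genotyping array) and per-population drift
`F = 0.02`, which — with the 10-founder mosaic process adding its own
drift — realises pairwise panel Fst near 0.1. Simulated
admixture uses a single shared event across targets, so those studies fit
the joint (`shared_Pi`) model variant — with two chromosomes per
individual, per-target switch matrices are badly overfit, while the
shared variant matches the generating process exactly. Real cohorts with
individually varying admixture histories should keep the per-target
default. The bundled studies also disable phase hunting (`rephase =
FALSE`): the simulator emits exactly phased targets, and re-phasing those
to the (slightly different) maximum-likelihood phase merges a few true
ancestry switches and biases dates downward at sparse densities. Phase
hunting earns its keep — and is separately validated — on input that does
carry phase errors, which is the situation of any statistically phased
real cohort.

Tolerances: EM monotonicity is enforced at 1e-6 relative (violations
raise an error, as they indicate a bug, not noise); the final EM stops at
5e-7–1e-5 relative log-likelihood change depending on the study; curve
fits use `minpack.lm` with a maximum of 200 iterations. All randomness
flows from a single user-supplied seed per run; identical seeds give
bit-identical results.

## Known limitations

* At 10 markers/cM the posterior cannot resolve tracts much shorter than
  ~0.5 cM; r² against truth plateaus near the ceiling set by the data
  (≈ 0.6–0.8 in the bundled studies), not at 1.
* Dating from posterior-probability curves is biased downward at sparse
  densities (see above); the MAP-track default removes most, not all, of
  the bias.
* `Pi`'s diagonal is confounded with `rho`; do not interpret it.
* A single pulse per ancestry pair is assumed; continuous gene flow or
  multiple waves show up only as poorly fitting curves and wide bootstrap
  intervals.
* Chromosome-bootstrap ±2 SE date intervals are mildly anti-conservative
  when only a handful of chromosomes provide the resampling units (measured
  coverage ≈ 70% with four); treat them as rough guides at desk scale.
* The selection scan's p-values are exploratory; no multiple-testing or
  genome-wide calibration is claimed.
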