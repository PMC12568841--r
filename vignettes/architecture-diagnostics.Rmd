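---
title: "Diagnosing processing architecture in composite-stimulus categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing processing architecture in composite-stimulus categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sftrules)
```

# The scientific problem

When an observer categorizes a composite stimulus — here a schematic
face whose top half varies in eye separation and whose bottom half in
lip-to-nose height — the two halves may be processed one at a time
(serially), concurrently but independently (in parallel), or pooled into
a single evidence stream (coactively). Coactivity is the strongest
operationalization of "holistic" processing; the weaker notions are
mimicked by many models, which is why the double-factorial paradigm and
Systems Factorial Technology (SFT) are needed.

The design is a 3×3 grid: three levels per dimension, a conjunctive
target category (both dimensions at their upper two levels, so 4
stimuli), and a 5-stimulus contrast category containing the redundant
stimulus `R` (low on both), the interior stimuli `Ix`, `Iy` (one step
from a bound) and the exterior stimuli `Ex`, `Ey` (two steps). The four
target items are crossed factorially in discriminability (LL, LH, HL,
HH), which licenses the interaction contrasts.

# Nonparametric statistics

`mic()` is the double difference of mean correct target RTs,
`sic()` the same contrast applied to survivor functions; the step-curve
integral of the SIC equals the MIC, which `sic_integral()` verifies
exactly on the pooled-unique-RT grid (the default `t_grid`; a regular
lattice can be supplied for plotting). Correct trials only enter these
statistics: error RTs are handled by the parametric models.

Architecture is read off the curves with the published conventions:

* serial exhaustive → MIC ≈ 0, S-shaped SIC with equal positive and
  negative areas;
* parallel exhaustive → MIC < 0, entirely negative SIC;
* coactive → MIC > 0, small early negative deflection then a dominant
  positive one.

Interpretability requires stochastic dominance of the survivor
functions, checked by eight one-sided Kolmogorov–Smirnov tests
(`ks_dominance_suite()`): the four ordered comparisons should be
significant and their reversals should not.

## Deflection tests

The maximum (`D+`) and absolute minimum (`D−`) of the SIC are tested
against a null of no distributional differences. The default backend is
a permutation test that reshuffles the pooled RTs over the four factorial
cells, preserving cell sizes — equivalent to permuting the H/L labels
within each dimension. An asymptotic backend uses the sup-Brownian-bridge
tail `p = exp(−2 m D²)` with `m = 1 / Σ(1/n_i)`; the two agree on the
null case and closely on moderate samples. The permutation default was
chosen because it is exact under exchangeability at any n; the replicate
count (default 1000) and the bootstrap-band settings of `sic()` (1000
replicates, 95% percentile envelopes) are configurable because published
analyses rarely state them.

## From statistics to labels

`classify_architecture()` makes the verbal reading of (SIC shape, MIC,
interior-vs-exterior pattern) computable. Shape tokens are produced by
thresholding the deflection tests: *positive* if only `D+` is
significant, *mostly negative* if only `D−`, otherwise *S-shaped*. Two
points where the design was genuinely open:

* When both deflections are individually significant the S-shape itself
  is reliable and both a coactive and a serial reading are listed — this
  is the only way to make the published summary table a function of its
  inputs, because two of its rows print identical triples yet different
  verdicts, and they differ precisely in joint deflection significance.
* A *mostly negative* SIC normally reads parallel self-terminating, but
  slower interior than exterior items contradict parallel
  self-termination, so that combination lists the serial reading as
  well. This follows the table's stated interpretation order (SIC, MIC,
  then interior/exterior).

The MIC token carries its sign when significant: a significant negative
interaction supports parallel processing, a positive one coactivity.

# The logical-rule models

Perception is General Recognition Theory: the percept of each dimension
is Gaussian with mean fixed at the stimulus's psychological coordinate
(from MDS; means must be fixed for drift rates to be identifiable) and a
freely estimated per-dimension SD. Integrating the marginal against the
decision bound gives the drift of the target accumulator on that
channel; the contrast accumulator receives the complementary mass, so
the two drifts sum to one exactly. The coactive model pools dimensions:
one channel whose target drift is the bivariate mass in the conjunctive
region (a product, by perceptual independence).

Channels are Linear Ballistic Accumulator races: start points uniform on
[0, A], drift drawn per trial from Normal(v, s), finishing time
(b − start)/rate, shared thresholds `b_target`/`b_contrast` across
channels. RT = decision time + t0 (all times in ms). Two conventions
that the LBA itself leaves open: a start point drawn above threshold
resolves immediately (time 0), and trials on which both sampled rates
are non-positive are resampled with a bounded retry — the task has a
response deadline and non-responses are not modelled.

Composition follows the self-terminating AND logic. Serial: one channel
at a time (lips first with probability `p_x`); a contrast resolution
terminates; a target response requires both channels and sums their
times — so for target items serial self-termination is effectively
exhaustive and the additive MIC prediction follows. Parallel: both
channels race; the response is contrast at the first contrast
resolution and target at the slower channel's time only when both
resolve target. The serial–parallel mixture draws the component per
trial (`p_serial`), with the parallel component's perceptual SDs
multiplied by `m` and its own start range `A_parallel`. Contaminant
variants replace a fraction `p0` of trials with uniform RTs over the
condition's observed range and a fair-coin response (the response rule
is unstated in the literature; a coin is the least-informative choice).
The free-drift model replaces the GRT block with nine per-stimulus
drifts.

## Reference parameterizations

`signature_spec()` is the canonical demonstration of the three MIC
signatures: level coordinates (−1, 0.75, 2), unit perceptual SDs, bounds
at 0 (standardized target distances 2.0 and 0.75), A = 300, both
thresholds 1500, s = 0.10, t0 = 250. The drift-rate SD is deliberately
small: the SFT signatures are predictions for the high-accuracy regime,
and because an LBA finishing time is distance/rate, drift draws near
zero produce extreme times whose influence on *mean* correct RT can
swamp the architecture effect. At s = 0.25 with these drifts the
coactive model's correct-RT MIC is either negative (error truncation
dominates) or unstable across seeds (near-divergent 1/rate tail); at
s = 0.10 the three signatures are large, stable multiples of their
Monte-Carlo standard errors.

`study_spec()` parameterizes study-scale generators (400 trials per item
per participant, sessions 2–8) to land in the descriptive envelope of a
human session: median correct RTs roughly 1–2.5 s, accuracy .85–1,
strongly overlapping item distributions. The coactive variant keeps a
higher threshold and smaller s because its overadditivity grows with the
accumulation scale. The serial–parallel mixture uses m = 2,
A_parallel = 200 and s = 0.2: error rates on the L items then fall at
5–15%, which both matches the observed range and keeps the decision
bounds and the mixing weight identifiable — with near-equal components a
pure serial model reproduces the mixture's likelihood at this sample
size and no method could recover the mixture from these data.

# Simulation-based inference

`pda_loglik()` approximates the likelihood by simulation: for each
stimulus, `n_sim` (response, RT) pairs are drawn fresh, each response
class contributes a defective density — its simulated proportion times a
Gaussian-kernel estimate with Silverman's bandwidth — and each observed
trial contributes the log of that density, floored at 1e−10 so
unsupported observations stay finite. The kernel estimate is computed on
the log-time scale (and transformed back), because RT distributions are
right-skewed: on the raw scale a single extreme simulant stretches the
512-bin grid and the evaluation noise roughly triples. With that choice
the evaluation SD on a 3600-trial dataset is ≈ 3.5 log-units at
n_sim = 10,000 and ≈ 1.9 at 50,000. Densities are estimated per
(stimulus, response) cell; fresh simulation per call makes the
estimator pseudo-marginal.

`de_mcmc()` samples with differential-evolution proposals
θ\* = θ_i + γ(θ_j − θ_k) + ε, γ defaulting to 2.38/√(2d), jitter ε
uniform on ±0.001, Metropolis acceptance, uniform box priors (ranges in
`default_priors()`: σ in (0.01, 5) perceptual units, bounds within the
coordinate span ±2, A and A_parallel in (0, 3000), thresholds in
(1, 5000), s in (0.05, 1), t0 in (50, 1000) ms, probabilities in (0, 1),
m in (0.1, 10), free drifts in (0, 1)). Three supports for the noisy
likelihood, all off by default in `de_mcmc()` and on in
`fit_rule_model()`:

* *refresh* — the stored log density of the current state is
  re-evaluated every k-th iteration, preventing chains from freezing on
  lucky overestimates;
* *burn-in migration* — every few iterations during burn-in the
  worst chain restarts at the best chain's position; retained samples
  are unaffected;
* *mode-centred initialization* — iterated candidate screening
  (cross-entropy style, on a cheap n_sim/5 surface) followed by a
  Nelder-Mead polish of the incumbent on the full surface; chains start
  in a tight ball around the polished mode. Short runs then yield usable
  posterior summaries; diffuse-start runs of the same length sit far
  above the mode and make deviance-based comparison meaningless.

`dic()` implements DIC = D̄ + 2 p_D with p_D = D̄ − D(θ̄) and θ̄ the
per-parameter posterior mean; `dic_weights()` uses the Akaike-style
transform w_i ∝ exp(−ΔDIC_i/2), which reproduces the published weights
from the published DICs.

# Confirmatory MDS

Ratings (1 = least similar … 8 = most similar; 36 pairs × 3 repetitions)
are converted to dissimilarities as 9 − rating — the simplest
order-reversing map; the per-participant INDSCAL weight absorbs scale.
The model distance is w_p · (Σ|Δcoord|^r)^(1/r). Coordinate modes:
*free monotone* (16 parameters: per-stimulus coordinates, anchored at
(0,0), increasing along each dimension within every row and column of
the grid) and *constrained grid* (4 parameters: shared level spacings).
Weights are constrained to geometric mean 1 (log-weights summing to
zero) for scale identifiability, but the BIC's k counts one weight per
participant, matching the published parameter accounting. The SSD is
minimized by multi-start quasi-Newton (`nlminb`) on an unconstrained
reparameterization (positive increments via log); the free Minkowski
exponent is logistic-mapped into [1, 5]. Absolute BIC values depend on
the likelihood normalization (concentrated Gaussian,
BIC = n·ln(SSD/n) + n(1 + ln 2π) + k·ln n) and are comparable only
within a dataset; all conclusions rest on rankings.

Participants are screened before fitting: anyone not using all eight
response options, or whose two most frequent options exceed 60% of
responses, is removed (`screen_participants()`; the threshold is
configurable).

# Composite-task signal detection

"Different" trials are signal; d′ = z(H) − z(F) and
c = −(z(H) + z(F))/2 with the 1/(2N) correction for extreme
proportions. The generator draws evidence from N(d′, 1) vs N(0, 1) and
responds "different" above d′/2 + c: the criterion is midpoint-referenced
so that c = 0 is the unbiased observer and the generated c is exactly
what the estimator recovers. Defaults build in the holistic marker — an
aligned congruency effect of 0.6 d′ units that shrinks to 0.2 when
misaligned (interaction 0.4) — with 36 participants, 128 trials per
cell, and a 0.2-SD participant offset. The 2×2 repeated-measures ANOVA
tests each effect against its own participant-interaction error term;
when an effect's sum of squares is exactly zero its F is reported as 0
rather than 0/0.

# What the generators do and do not emulate

The RT generator reproduces the design's structure (9 stimuli × 400
trials over sessions 2–8, both alignment conditions, RTs in the plausible
200–5000 ms band) and the architecture-specific distributional
signatures, with independently seeded per-participant streams. It does
not emulate session-level learning unless the optional linear speed-up
is enabled, attention lapses beyond the contaminant models, or
trial-to-trial sequential effects. The similarity-rating map (linear in
distance with Gaussian noise, clamped to the scale ends) is a stand-in:
no generative model of human ratings is implied by the source analyses.
Passing recovery tests therefore demonstrates internal consistency of
the pipeline — estimators recover what the models generate — not that
the models capture every feature of human data.

# Verification scales

The test suite exercises every stage at sizes chosen to make its checks
sharp yet re-runnable: signature MICs at 50,000 trials per item against
3 bootstrap SEs; the SIC–MIC integral identity on 100 random datasets at
1% of the RT range; the LBA simulator against numerical integration of
the analytic first-passage density at n = 10⁶ (< 1% error); ANOVA F's
against brute-force sums of squares at 1e−9; DE-MCMC against an analytic
Gaussian; parameter recovery of the serial–parallel mixture on five
seeds at 400 trials per item with n_sim = 10,000 (p_serial within ±0.15,
bounds within ±0.25); DIC selection on ten datasets (twenty fits, four
generating architectures) at shortened chain settings; MDS model
recovery on ten seeds (15 participants); and the composite-task
interaction on ten seeds at the 36-participant scale. Fits use the
mode-centred pipeline described above; fully converged reference runs
use the 3d-chain default with several hundred iterations.

# Known limitations

* The deflection permutation null assumes exchangeability of all four
  cells (a complete null), which is conservative for testing the
  interaction only.
* Pure-architecture generators at high discriminability produce larger
  SIC deflections than typical human data, where mixtures and noise
  dilute them; deflection-test power statements are regime-specific.
* DIC with short, mode-centred chains under-disperses the posterior, so
  p_D is approximate; model rankings in the tests rest on deviance gaps
  an order of magnitude larger than this error.
* PDA likelihoods are biased at finite n_sim (kernel smoothing); the
  bias is shared across models compared on the same data.
* The coactive model is a single race with the pooled bivariate drift;
  explicit channel-summation dynamics are not implemented.
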