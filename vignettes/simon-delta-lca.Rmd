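---
title: "Distributional analysis of Simon-task congruency and the extended LCA simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional analysis of Simon-task congruency and the extended LCA simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(simonlca)
library(dplyr)
```

## The problem

In the Simon task, participants respond to a non-spatial stimulus feature
(here: colour) while the task-irrelevant stimulus position primes the
spatially corresponding response. Responses are faster and more accurate
when stimulus and response positions correspond (congruent) than when they
do not (incongruent). The size of this congruency effect (CE) changes over
the reaction-time (RT) distribution, and that time course — summarised by
*delta plots* — interacts with strategic speed-accuracy settings: when delta
plots decrease with RT, the slower responding induced by accuracy
instructions lowers the mean CE; when they increase, it raises it.

The package implements the full analysis chain for a design that
manipulates the stimulus-onset asynchrony (SOA) between the irrelevant
(position) and relevant (colour) feature: SOAs of −200, −100, 0, +100 and
+200 ms (negative = position first), crossed with speed vs accuracy
instruction sessions and congruency, with 24 participants and 40 trials
per cell (19 200 trials). RT is measured from the onset of the *first*
feature, so mean RTs at negative SOAs are longer by roughly the lead time.

## Analysis pipeline

Starting from trial-level data (`read_trials()` or
`simulate_experiment()`), `run_analysis()` chains:

1. **Outlier filter** — trials with RT < 100 ms or no recorded response are
   removed; this is the only trial-level exclusion. The boundary is
   strict (a 100 ms trial is kept), and missing responses are excluded
   from error-rate denominators rather than counted as errors.
2. **Cell summaries** — per participant × instruction × SOA × congruency:
   error rate over responded trials, mean correct RT, and the correct-RT
   quantiles at levels .1/.3/.5/.7/.9. One quantile estimator is used
   everywhere: linear interpolation at position *h* = (*n* − 1)*p* + 1
   (`stats::quantile` type 7).
3. **Delta plots** — per cell pair, the CE at each quantile level
   (incongruent − congruent) against the mean of the two quantiles.
4. **Overlap-range slopes** — OLS slope of each delta plot restricted to
   the quantile levels where the two instructions' RT ranges roughly
   overlap: .3–.9 under speed, .1–.7 under accuracy instructions.
5. **Overlap centres and cubic levels** — the centre of the group-level
   overlap interval (midpoint between the group-mean accuracy .1 abscissa
   and the group-mean speed .9 abscissa, one per SOA), and each
   participant's third-order polynomial fit through the five delta-plot
   points evaluated at that shared RT. This compares delta-plot *levels*
   at identical RTs, removing the trivial effect of accuracy instructions
   shifting responses rightward.
6. **Binned error CEs** — six RT bins per cell, bounded by that
   congruency cell's own correct-RT quantiles (standard conditional
   accuracy practice); bin-wise error-percentage difference incongruent −
   congruent.
7. **Inference** — a three-way repeated-measures ANOVA
   (instruction × SOA × congruency) on mean RTs, an instruction × SOA
   ANOVA on slopes, a one-way SOA ANOVA on speed−accuracy level
   differences, Friedman tests of the error-rate CE across SOAs per
   instruction, Wilcoxon tests of that CE against zero, group slope means
   with 95% t-based confidence intervals, and Cousineau–Morey
   within-participant standard errors for figures.

Design choices worth stating explicitly:

* **Per-participant analysis.** Slopes and cubic levels are computed per
  participant and then aggregated, because the inferential tests carry
  participant degrees of freedom.
* **Overlap centre rule.** "Centre of the overlapping range" is read as
  the midpoint of the interval from the group-mean lowest accuracy
  abscissa to the group-mean highest speed abscissa. With an empty
  overlap the function refuses rather than extrapolating silently.
* **Cubic support.** The cubic is fitted to all five delta-plot points of
  a cell (five points are the minimum sensible support for degree 3);
  only the *evaluation* point is restricted to the overlap centre.
  Evaluations outside the fitted range are permitted but flagged.
* **Bin boundaries.** Error bins use each congruency cell's own
  quantiles, and boundary ties go to the lower bin (right-closed
  intervals) — an arbitrary but fixed convention.

## The repeated-measures ANOVA

For a balanced fully-within design with one score per participant per
cell, each effect is projected onto an orthonormal contrast basis (the
Kronecker product of polynomial contrasts for factors in the effect and
normalised averaging vectors for the rest). With transformed scores
*Z* (participants × *d*), the effect and error sums of squares are
*n*‖*Z̄*‖² and ‖*Z* − *Z̄*‖², and the effect is tested against its own
participant interaction. Partial eta squared is
SS(effect)/(SS(effect)+SS(error)). The Greenhouse–Geisser epsilon is
computed per effect from the eigenvalues λ of the covariance of *Z*:
ε = (Σλ)²/(*d*·Σλ²), which is 1 exactly under sphericity and bounded
below by 1/*d*; the corrected p uses (ε·df₁, ε·df₂). Both the uncorrected
and corrected p are always reported and the caller chooses (the classic
practice is to use the correction when *k* > 2).

Error percentages are skewed, so their CEs are tested nonparametrically:
Friedman's chi-square over SOAs and the Wilcoxon signed-rank test against
zero. The Wilcoxon statistic is the smaller signed-rank sum with
mid-ranks for ties and dropped zeros; its p-value uses the tie-corrected
normal approximation with continuity correction, so exact-enumeration
software can differ in the third decimal.

## The extended leaky competing accumulator

Two response accumulators *x₁* (correct) and *x₂* race to an
instruction-dependent threshold θ:

dx_i = (I_i − k·x_i − β·x_j) dt + σ√dt·ξ,  x_i ≥ 0,

with leak *k*, lateral inhibition β, and a zero floor — the canonical LCA
— extended by two ingredients the SOA design requires: the two routes
switch on at their feature onsets plus perceptual delays
(`d_rel`, `d_irr`), and the irrelevant route's input decays
exponentially, *A*·exp(−lag/τ), feeding *x₁* on congruent and *x₂* on
incongruent trials. The response is the first accumulator to reach θ; RT
adds a non-decision time `t_nd`; no crossing before the deadline is a
missing response. Integration is Euler–Maruyama at `dt` = 1 ms (the
noise-free crossing times move by well under 1 ms when `dt` is halved).
Speed vs accuracy instructions differ only in θ by default
(`theta_speed` ≤ `theta_accuracy`); optional `A_accuracy`/`tau_accuracy`
overrides let the irrelevant influence itself depend on instruction.

### Default parameters and what they were calibrated to

The shipped defaults (`lca_params()`) were chosen, by simulation, to
reproduce the qualitative empirical pattern of the design rather than any
single data set:

| parameter | default | units | role |
|---|---|---|---|
| `theta_speed`, `theta_accuracy` | 4, 4.3 | activation | response caution per instruction |
| `k` | 0.03 | 1/ms | leak; memory of early input ≈ 33 ms |
| `beta` | 0.002 | 1/ms | lateral inhibition (weak) |
| `drift` | 0.132 | act./ms | relevant-route input |
| `A`, `tau` | 0.23, 20 | act./ms, ms | irrelevant pulse height and decay |
| `sigma` | 0.245 | act./√ms | diffusion noise |
| `t_nd` | 190 | ms | non-decision time |
| `d_rel`, `d_irr` | 135, 12 | ms | perceptual delays (colour vs location) |

Under the standard design these produce mean RTs of roughly 380–560 ms
across SOAs, error rates of a few percent (higher under speed
instructions), mean-RT CEs of ~15–40 ms at every SOA, delta plots that
*decrease* with RT at SOA ≤ 0 and *increase* at positive SOAs, and error
CEs concentrated in the fastest bins at SOA ≤ 0.

The mechanism behind the sign pattern is worth recording because it
constrained the calibration strongly. The irrelevant drive is a brief,
early pulse (τ = 20 ms) that is processed much faster than the colour
(d_irr ≪ d_rel). At SOA ≤ 0 the pulse has largely played out before the
relevant route engages: its trace decays at the leak rate, so it affects
only the fastest responses — including occasional outright captures
(irrelevant-route threshold crossings: fast errors when incongruent, fast
correct responses when congruent) — giving large CEs at the .1 quantile
that vanish later, i.e. decreasing delta plots. At positive SOAs the
pulse instead arrives while decisions are under way; responses that
happen to finish first escape it, slower ones absorb it fully, so the CE
grows with RT. A long-memory configuration (small *k*, large τ, strong
inhibition coupling) would instead let early conflict persist into the
slow tail and *increase* delta plots at SOA 0; the short-memory regime is
the one that reproduces the empirical pattern, which is why the defaults
sit there. The 123 ms gap between `d_irr` and `d_rel` encodes the
well-known speed advantage of location over colour processing and is the
lever that makes the SOA 0 condition behave like a weak negative SOA.

Between-participant heterogeneity is modelled as mild log-normal jitter
(mean 1, CV 0.1 by default) on the thresholds (one shared factor, so the
ordering is preserved), `drift`, `A`, `tau` and `t_nd`. The value is a
conventional "mild individual differences" choice; it exists so that
group-level analyses see realistic spread, and it is not fitted.

What the generator does *not* emulate: trial-to-trial sequential effects
(congruency-sequence adaptation), fatigue or practice drifts, RT
anticipations below 100 ms, and technical response failures (missing
responses arise only from the deadline). Passing tests on synthetic data
therefore validate the analysis machinery and the model's qualitative
adequacy, not any claim about a particular empirical data set.

## Model fitting and recovery

`quantile_targets()` compresses each instruction × SOA × congruency cell
(pooled over participants) into defective bin probabilities: the
correct-response mass in the six bins bounded by the cell's observed
correct-RT quantiles, plus the error proportion. `lca_objective()`
simulates candidate parameters (re-seeding identically on every call —
common random numbers — so the search surface is deterministic), bins the
simulated trials by the *observed* boundaries, and sums Pearson
chi-square discrepancies; expected counts are floored at 0.5 and empty
simulated cells incur a large penalty instead of an error.

`fit_lca()` minimises this with a bounded derivative-free search: a
log-space scan of the box, two rounds of local perturbation around the
incumbent alternating with Nelder–Mead descents (the local jumps step
across the flat plateaus that binned objectives produce), and a
floor-based safeguard — if the best value still exceeds 2.5× the
chi-square sampling floor (1 + n/n_sim)·6·cells, one fresh scan round is
spent from a shifted seed. By default only `theta_speed`,
`theta_accuracy`, `A` and `tau` are free; `k`, `beta`, `drift` and
`sigma` stay fixed because they form ridges with the free set (σ is the
scale parameter of the model, and (A, τ) trade off against each other
along an iso-peak-height ridge).

That ridge dictates the recovery design in `parameter_recovery()`:
fitting cells at SOA 0 and +100. The zero-SOA cells pin the thresholds
and the pulse height; the +100 cells, where the pulse arrives
mid-decision, are the ones whose quantile profile is sensitive to the
decay *length* and so break the (A, τ) ridge. With the standard design
size (960 trials per cell pooled over participants, jitter off, as in a
standard recovery study) the median relative recovery errors over ten
seeded replicates are below 1% for both thresholds and roughly 5–12% for
A and τ.

## Numerical conventions and degenerate inputs

* Quantile estimation, bin assignment (right-closed), and the 100 ms
  strict boundary are each implemented in exactly one internal helper.
* Cells with zero correct trials, empty overlap intervals, incomplete
  ANOVA designs, all-zero Wilcoxon differences, and non-PSD covariance
  inputs raise errors naming the offending cell or interval; empty RT
  bins propagate as `NA` with a warning.
* Accumulator ties at threshold resolve in favour of the correct
  accumulator; at σ = 0 the integration is deterministic and matches an
  independent R-side ODE integration exactly.
* All simulation randomness flows from a single seed; `simulate_experiment()`
  records design, parameters, seed and per-participant parameter sets in
  the output's provenance attribute.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full standard design
(24 × 2 × 5 × 2 × 40) for the sign-pattern and descriptive checks, 1000
replicates of a 24 × 5 null for type-I calibration (the ANOVA null uses a
non-spherical covariance — AR(1) correlation 0.65 with heterogeneous
variances, ε ≈ 0.69 — because that is the regime the Greenhouse–Geisser
correction exists for; under a spherical null the corrected test is
deliberately conservative, and the rank tests keep their exchangeable iid
nulls), ten seeded replicates for parameter recovery (budget 700
objective evaluations, 1000 simulated trials per cell per evaluation),
and reduced designs (6–10 participants, 24–40 trials per cell) for the
structural pipeline tests. These sizes
were chosen to keep each property's sampling error well below the margins
being asserted.

## Known limitations

* The accumulator extensions (staggered onsets, exponentially decaying
  irrelevant drive, zero floor, instruction-dependent threshold) are one
  defensible formalisation of the dual-route account; other variants
  (nonzero starting baselines, instruction-dependent non-decision time,
  active suppression instead of passive decay) are not implemented.
* Group-level fitting only: no hierarchical participant-level estimation.
* The Wilcoxon p-value is a normal approximation; with n = 24 and ties
  this is standard but not exact.
* No correction for multiple testing across SOAs or instructions is
  applied, matching common practice for this design.
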