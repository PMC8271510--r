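---
title: "Scoring basketball passes with qpass: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring basketball passes with qpass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpass)
```

## The measurement problem

Field tests of basketball passing are usually scored by hit counts alone,
which separates skill levels poorly: a pass can hit the target slowly, or
with an erratic arm action, and still count the same as an expert pass.
`qpass` implements a multifactorial alternative: each executed pass receives
a 0-100 quality score (the Q-Pass index) built from three penalty factors,

* **f1 — accuracy**: where the ball hit relative to a 0.61 m × 0.61 m wall
  target, discretised to the five penalties {0, 25, 50, 75, 100};
* **f2 — execution time**: how far the pass duration deviates from a
  reference execution time;
* **f3 — pattern variability**: how far the pass's arm-movement pattern,
  summarised by one number, deviates from a per-pass-type reference pattern.

The kinematic signal behind f3 comes from two gyroscopes worn on the
dominant arm (wrist and medial humerus) sampled at 128 Hz. Their 3-axis
angular-velocity vectors are summed componentwise and reduced to the
magnitude $|gyr_1 + gyr_2|$ per sample, low-pass filtered, and integrated
over the annotated pass window with a left-endpoint rectangle rule:
$\Delta t \sum_i |gyr_1 + gyr_2|_i$, with $\Delta t = 1/f_s$. Two identical
executions produce identical curves, hence identical integrals, so the
spread of this integral across repeated passes measures movement
variability; each execution is penalised by its absolute deviation from the
reference integral of its pass type.

Raw penalties become natural numbers (absolute deviations rounded to the
nearest integer), are normalised so the worst execution in the pool maps to
exactly 100, and are flipped to qualities $q = 100 - p$. The index of one
execution is the weighted combination

$$\mathrm{QPass} = x_1 q_1 + x_2 q_2 + x_3 q_3,
\qquad x_1 + x_2 + x_3 = 1,$$

and a player's score per pass type is the *modified mean* over repeated
executions: the mean after discarding one maximum, one minimum and one
median value.

### References come from a skilled group

Both deviation factors need an anchor. `qp_reference()` computes it from a
designated reference group (by default the experienced "A" group):

* the reference execution time `Ex_Tr` is the mean duration, in samples, of
  the *quickest* pass type in that group (the chest pass, in practice);
* the variability reference `ExPT_ir` is, per pass type, the mean pattern
  integral over the group's executions — five references in total.

References are serialisable (`write_reference()`), so a coach can freeze a
skilled cohort's references and score new players against them.

## Assumptions

* Pass windows are **annotated**, not detected: start (ball reception) and
  end (ball release) sample indices come from an external source such as
  synchronised video. No movement-onset detection is attempted.
* Recordings are uniformly sampled; traces whose time stamps deviate from
  `1/fs` by more than a relative `1e-6` are rejected rather than resampled.
* Angular velocities are in deg/s. The unit only rescales the f3 deviations
  uniformly and cancels in the max-to-100 normalisation, so a rad/s cohort
  would produce identical scores.
* Scores are cohort-relative: normalisation uses the pool being scored, so
  an index of, say, 80 is comparable within a cohort (or against a frozen
  reference) but not across unrelated cohorts.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `weights` (x1, x2, x3) | (1/3, 1/3, 1/3) | — | The weighting is a coaching decision (e.g. weight accuracy more for mature throwers); equal weights are the neutral default. |
| `fs` | 128 | Hz | Sampling rate of the arm-worn sensors. |
| `filter.cutoff_hz`, `filter.order` | 25, 4 | Hz, — | Low-pass Butterworth retaining voluntary arm movement while rejecting sensor noise and impact transients. |
| `f2_pool` | `"cohort"` | — | Pool for f2 normalisation. Durations are comparable across pass types, so the time factor is normalised over all executions; the variability factor is always normalised per pass type, because the integral scale differs strongly between types. Set `"per_pass_type"` to normalise f2 within types instead. |
| `bin_edges` (f1 geometric scorer) | (1/3, 2/3) | fraction | Operationalise "most of the area inside/outside" when ball-impact geometry replaces manual category assignment. |
| `group` (reference) | `"A"` | — | Which group defines `Ex_Tr` and `ExPT_ir`. |

## Numerical choices

* **Magnitudes.** Vector magnitudes are Euclidean norms; the combined
  signal is the norm of the componentwise sum of the two sensors' vectors,
  computed per sample *before* filtering.
* **Zero-phase filtering.** The 4th-order design is applied forward and
  backward so event timing inside windows is not shifted; the effective
  magnitude response is the square of a single pass. Edges are handled by
  odd-reflective padding of `3 * (order + 1)` samples, and each pass is
  anchored at its first value so the zero-state start of the IIR recursion
  sees no step. Recordings are filtered in full before windows are sliced,
  which keeps nested windows consistent and avoids per-window transients.
* **Windows** are half-open `[start, end)` in 0-based sample indices, so
  `n = end - start` exactly and contiguous windows partition a recording;
  elapsed time is `n / fs`.
* **Integration** is the left-endpoint rectangle rule `dt * sum(values)`:
  additive over partitions, homogeneous, and within one rectangle of the
  trapezoid rule on monotone segments (asserted in the tests).
* **Rounding** of raw penalties is half-away-from-zero ("nearest natural
  number" without banker's bias). The f2 deviation is counted in
  **samples**, the unit in which durations are measured here; on the
  seconds scale nearly every deviation would round to zero, making the
  rounding step meaningless.
* **Degenerate pools.** An all-zero penalty pool (every execution perfect)
  normalises to all zeros instead of dividing by zero.
* **Modified mean ties.** Exactly one maximal, one minimal and one median
  element are removed by *position in the sorted order*; for even lengths
  the lower of the two middle order statistics is the median. This makes
  the estimator deterministic under ties.
* **Overlap geometry.** The optional accuracy scorer models the ball print
  as a circle and computes the exact circle-square intersection area by
  piecewise adaptive quadrature (pieces split where the circle crosses the
  square's horizontal edges); full containment and no-overlap are returned
  exactly. A print that touches a boundary line cannot earn penalty 0.

## Design choices on genuinely open points

* **Penalties vs. qualities.** The three factors are defined as penalties,
  yet the index must be a 0-100 score on which skilled players rank
  *higher*. The package therefore converts normalised penalties to
  qualities `100 - p` and combines qualities. This is the only direction in
  which "better execution, higher score" holds.
* **Student's t, pooled variance.** Group comparisons use the classical
  equal-variance t-test (preceded in the original workflow by a Levene
  screen), not Welch's variant.
* **Hedge's correction.** `J = 1 - 3/(4N - 9)`, the standard small-sample
  correction of the effect-size spreadsheet tradition; an exact
  gamma-function `J` is available via `hedges_g(..., exact = TRUE)`.
* **Percent change** is reported with the lower-scoring group as base by
  default, but the base is configurable because "x% greater" phrasing does
  not identify its denominator.
* **No multiplicity correction** is applied to the per-pass-type p-values;
  they are reported raw.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *design* of a two-group passing study:
2 groups × 8 players × 5 pass types × 25 executions (5 targets × 5 passes)
at 128 Hz. Each pass is a smooth raised-cosine (Hann) burst of the combined
angular-speed magnitude, split 65:35 between wrist and humerus along a
common direction, bracketed by 1-2 s of low-noise baseline so
full-recording filtering is realistic. The burst is band-limited well below
the 25 Hz cutoff, so filtering is nearly transparent and the pattern
integral has the closed form `peak * duration / 2` used as a test oracle.

Group defaults encode the skill contrast: the experienced group is faster
(chest ≈ 0.50 s mean duration, the quickest type; the novice group ≈ 15%
slower), stronger at the peak (600-900 deg/s vs. 10% less), more accurate
(categorical accuracy draws concentrated on penalties 0/25) and less
variable (shape jitter 0.06 vs. 0.15, duration SD 0.05 s vs. 0.09 s).
Players within a group differ by a multiplicative log-normal spread (SD
0.10) in tempo and vigour, giving between-player score SDs of a few points,
the heterogeneity typical of an adolescent cohort. All draws flow from one
explicit seed; a truth table records every drawn parameter, and the
caller's RNG state is restored.

The generator is *not* a biomechanical simulation: it has no multi-joint
kinematics, no ball flight (accuracy is drawn categorically, not derived
from a trajectory), no accelerometer/magnetometer channels, and its
single-burst shape cannot produce the double-peaked patterns a
dribble-then-pass sequence can show. Passing tests on synthetic cohorts
therefore demonstrates that the scoring pipeline is correct and sensitive
to the injected skill contrast — not that the index has any particular
reliability on real players.

## Validation problem sizes

The test suite validates the statistics at the sizes that keep the checks
sharp but fast: SEM recovery uses 50 subjects × 10 trials × 200 replicates;
the group-separation check runs the full default cohort over 100 seeds; the
null (identical-groups) effect-size check uses a reduced design (2 pass
types, 6 trials) over 100 seeds, where the median Hedge's g stays within
±0.4 of zero at n = 8 per group; byte-identical reproducibility is asserted
on the full simulate → reference → score → report chain.

## Known limitations

* Scores are only comparable under a shared normalisation pool or frozen
  reference; the index is ordinal-ish across cohorts.
* f1 is coarse (five categories), so with accuracy-heavy weights the index
  inherits its discreteness; per-execution accuracy dominates the
  within-player variance of the default-weight index.
* The SEM/CV treat successive executions as repeated measurements of a
  stable trait; learning or fatigue across 25 trials would inflate them.
* `Ex_Tr` is a single global time reference: every non-quickest pass type
  carries a structural f2 penalty. This is by design (quickness is part of
  quality) but means f2 differences between types are not pure skill
  differences.
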