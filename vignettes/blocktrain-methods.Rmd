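---
title: "Models and methods behind blocktrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind blocktrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocktrain)
```

`blocktrain` implements the measurement and analysis chain used to compare
two short interval-training blocks — moderate-intensity (MIT, heavy domain)
and high-intensity 30/15-s (HIT, severe domain) — in well-trained cyclists.
This vignette explains the models, the tunable parameters, the synthetic
cohort generator that stands in for athlete data, and the numerical and
design choices, so a reader can judge what a passing test suite does and does
not demonstrate.

## The measurement chain

### Lactate profile and thresholds

The incremental protocol starts at 125 W (175 W for riders self-estimating a
threshold above 325 W) with 5.5-min bouts; power rises by 50 W per bout until
any blood lactate reading is at or above 2 mmol·L⁻¹, then by 25 W until a
reading at or above 4 mmol·L⁻¹ ends the test. `next_step_power()` encodes
exactly this rule; the start-power branch is caller-supplied, never inferred.

The threshold power `po_at_lactate(profile, 4)` is the *piecewise-linear*
interpolation between the two bracketing steps — a local segment, not a
global regression, because a single line cannot represent the convex lactate
curve. Three deliberate edge rules:

* **No extrapolation, ever.** A level outside the observed lactate range is
  an error; callers needing the 2 mmol·L⁻¹ power for the 30-min bout use the
  same bracketing rule.
* **Exact hits return the step power** (the lowest matching step if several).
* **Flat segments** (ties in lactate) resolve to the lowest bracketing power
  — the conservative threshold.

Because the chord of a convex curve lies above it, interpolation slightly
*underestimates* the true root; with 25 W fine steps the error is bounded by
one increment and shrinks with denser protocols (both properties are tested).
Fractional utilization interpolates per-step %V̇O₂max against power with the
same bracketing rule.

### Gas exchange and energetics

Metabolic power input is linear in the energetic equivalent of oxygen:
`PI = V̇O₂ · (4840·RER + 16890)` J·s⁻¹ with V̇O₂ in L·s⁻¹. The equivalent is
undefined for net anaerobic exchange, so RER above 1.0 is clamped to 1.0 —
standard practice for substrate-mix equivalents; values above 1 indicate
non-steady-state CO₂ washout, not fat/carbohydrate balance. Gross efficiency
is mechanical over metabolic power, `GE = 100·PO/PI`, the orientation that
yields the 19–20% typical of trained cyclists.

V̇O₂max is the best 60-second rolling mean — defined in seconds, not samples,
so 5-s test sampling and 10-s session sampling both work. Aerobic energy
turnover over work intervals uses *duration-weighted* means (with uniform
sampling, the pooled sample mean); the test suite demonstrates that
per-interval totals only add up to the session total under duration
weighting. Time at or above 90% of V̇O₂max counts work-interval samples only:
whether recovery periods should count is not defined by the session tables
this mirrors, and "during the interval series" is read as work intervals.

### Training load

Zone cut points sit at 55/75/90/105% of the 40-min-trial reference. Published
zone tables display rounded, gapped ranges (55/56, 75/76, ...); the
implementation uses contiguous half-open bins with each cut assigned to the
upper zone so that every endurance minute lands in exactly one zone (the
partition property is a test). Both a power basis and a heart-rate basis are
supported; power is the default and the choice is recorded in the scheme
object. TRIMP is the zone-weighted minute sum, linear by construction.

### Performance outcomes and the composite index

The battery preserves the prolonged-test order (profile → sprint → V̇O₂max
test → 30-min bout at the 2 mmol·L⁻¹ power with repeated steps → 15-min
trial), which is what gives the fresh vs semi-fatigued efficiency labels: the
third- and second-last profile steps are re-ridden after the 30-min bout. The
endurance performance index is the mean of PO_V̇O₂max, PO₄ₘₘₒₗ and PO₁₅ₘᵢₙ
after dividing each by its maximum over the reference set. The reference set
defaults to *all* observations entering the analysis (both blocks, both
timepoints), since a pooled maximum is the natural reading when no timepoint
is singled out; a per-block reference is exposed as an option and the basis
is returned with results so any alternative is reproducible.

### Change analysis

Per-rider change scores (`delta = post − pre`, `pct = 100·delta/pre`) feed
three analyses:

* **Within-block**: paired t-tests on the deltas (labelled as such in the
  output — a mixed-model marginal-means contrast could differ slightly).
* **Between-block**: the design is within-subject, two-period, with complete
  pairs. Instead of restricted-maximum-likelihood mixed-model machinery, the
  block×time contrast is estimated by regressing each rider's *difference of
  deltas* on the (centered) *difference of baselines*; the intercept is the
  baseline-adjusted contrast. For complete balanced two-period data this is
  exactly the mixed model's block×time estimate (a test cross-checks it
  against `lme4::lmer` on simulated data); under missingness the two would
  diverge, which is the documented price of the simpler estimator. Its
  type-I error is verified at the nominal 5% by simulation.
* **Effect sizes**: Cohen's d in the two-sample pooled-SD form, because the
  interpretation scale used (trivial < 0.25 ≤ small < 0.5 ≤ moderate ≤ 1.0 <
  large, for highly trained subjects) is calibrated for that form; the paired
  standardized effect d_z is also reported, flagged as a supplementary
  number. Outcomes that are themselves percentages (gross efficiency,
  fractional utilization) are compared on %-point changes, routed by outcome
  metadata. Significance is two-sided at p ≤ 0.05 with no multiplicity
  correction, matching small-cohort sport-science practice.
* **Regressions**: ordinary least squares of a change score on a training
  variable, controlling for baseline and body-mass change (optionally sex),
  reporting the estimate, t-based 95% CI, p, and adjusted R².

Percent-change bookkeeping: the mean of per-rider percent changes is not the
percent change of the group means; both are computed (`mean_pct_*` vs the
group-mean arithmetic) and the reporting layer labels which is which.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed once and
are not tuning dials.

**Latent state.** Each rider draws body mass 70.8 (7.9) kg, V̇O₂max 69.5
(6.0) mL·min⁻¹·kg⁻¹, gross efficiency 19.7 (1.2)%, fractional utilization at
the 4 mmol·L⁻¹ threshold 79.2 (3.8)%, HRmax 195 (7) bpm, and a first-order
V̇O₂ time constant of 25 (4) s. Distributions are normal with physiological
clamping — the individual-level shapes are an assumption (population tables
publish only means and SDs), which is why clamped-normal is flagged rather
than claimed. One master seed governs everything through independent
per-rider sub-streams, so enlarging a cohort never perturbs existing riders.

**Lactate curve.** `La(P) = basal + amp·exp(rate·(P − P₄))` with
`amp = 4 − basal`, a convex monotone form common in threshold modeling, so
the latent `P₄` is the exact analytic 4 mmol·L⁻¹ root. The interpolation
stage can therefore be tested against a closed form. The 40-min maximal power
is tied to `P₄` (ratio 1.00 (0.03)), the 15-min power sits 7% above the
40-min power and is floored just above `P₄` so the ordering
PO₄ₘₘₒₗ < PO₁₅ₘᵢₙ < PO_V̇O₂max holds for every rider.

**Gas exchange.** Steady-state V̇O₂ demand at power P is `P/(GE·eq(RER))`
— gross, so measured efficiency recovers the latent value exactly in the
noise-free limit. RER rises linearly with relative intensity (0.82 + 0.18 ×
P/PO_V̇O₂max, clamped). V̇O₂ follows a single first-order system toward the
demand, saturating at V̇O₂max; there is no slow component. The maximal
incremental power exceeds the aerobic-only power by an anaerobic reserve
factor of 1.18 (0.05), which places PO_V̇O₂max near 5.9 W·kg⁻¹ for the
default cohort.

**Sessions.** MIT sessions ride continuous intervals at 97% of the 40-min
power; HIT sessions ride the 30/15-s pattern guided at 118%/60% of the 40-min
power, multiplied by an effort factor of 1.10 because such sessions are
RPE-guided (16–18) and riders settle above the nominal guidance — the factor
was fixed from the published session power arithmetic, not fitted. A
log-normal intensity jitter (4% SD) represents session-to-session effort
variation. The true pattern lives on a 5-s grid (the 45-s HIT cycle does not
exist on a 10-s grid); the emitted series averages sample pairs onto the
10-s mixing-chamber grid. Heart rate follows a slower first-order response
(45 s) toward a linear-in-power steady state, saturating at HRmax. RPE is a
configured constant plus noise — no perceived-exertion psychology is modeled.

**True effects.** `effect_config()` holds per-block mean (SD) percent changes
for the threshold power, maximal incremental power, 15-min power, sprint
power, V̇O₂max and body mass, plus %-point changes for efficiency; defaults
are the observed responses of the two blocks (MIT: threshold +4.5 (4.5)%,
15-min +4.9 (8.7)%, sprint −1.5 (7.3)%, ...; HIT: threshold +2.1 (2.7)%,
sprint +1.5 (3.7)%, ...). A washout drift of 1.5 (2.0)% between blocks
reproduces the slightly higher second-block baselines of a fixed-sequence
design. Measurement noise defaults: lactate 0.2 mmol·L⁻¹, V̇O₂ 2% per
sample, self-paced power 1%, heart rate 2 bpm.

**What the generator does *not* emulate.** No V̇O₂ slow component (so MIT
time ≥ 90% of V̇O₂max is near zero where real cohorts show a small, highly
skewed amount); no fatigue accumulation across a block, illness, dropout,
glycogen or thermoregulation; no sex-specific kinetics (the default cohort is
21 M / 1 F via configured means only). Passing recovery tests therefore shows
the *measurement chain* is faithful under the stated physiological model —
not that the model captures every feature of real athletes.

## Numerical choices and problem sizes

* Rolling means use moving-average filters; windows are defined in seconds.
* The V̇O₂max-test trace ends part-way through the stage where the rider's
  true maximal 1-min power is reached (partial stage rounded to the 5-s
  grid), so the last-minute mean load recovers the latent value to ~1 W.
* Degenerate inputs: a flat lactate curve yields a non-terminating profile
  (flagged, threshold refused); zero-variance change sets report a zero
  contrast with p = 1 and a zero effect size rather than dividing by zero;
  rank-deficient regression designs are refused naming the collinear term.
* Simulation sizes in the test suite: oracle property tests run up to 1000
  random series; the null-calibration of the block contrast uses 1000
  replicates at n = 22; regression-slope recovery uses 200 replicates; the
  end-to-end effect-recovery check uses 100 replicate studies at n = 22
  (each replicate simulates and re-measures 88 full test batteries). These
  sizes keep Monte-Carlo error well inside the asserted tolerances while the
  whole suite completes in a few minutes.

## Known limitations

* The between-block estimator assumes complete pairs; riders missing either
  timepoint in either block are excluded (with a count), unlike a
  mixed-model analysis that would use partial information.
* The generator's session model understates time near V̇O₂max for heavy-domain
  work (no slow component), so analyses relating that quantity to adaptation
  should be read as pipeline validation, not physiology.
* The index's reference maximum is sensitive to the chosen reference set when
  cohorts are pooled across studies; the basis is therefore always stored
  with results.
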