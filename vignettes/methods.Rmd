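---
title: "Methods: from OCR traces and cage bins to coupling thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OCR traces and cage bins to coupling thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitothermics)
```

## Overview

`mitothermics` chains four analyses that usually live in separate
spreadsheets: respiration-state extraction from plate OCR traces,
coupling thermodynamics (RCR, degree of coupling q, optimal efficiency
η-opt with Stucki set-point classification), circadian indirect
calorimetry, and proteome/copy-number statistics. This vignette explains
the model behind each stage, the tunable parameters, the numerical
choices, and what the bundled synthetic-data generator does and does not
emulate.

## Respiration states from plate traces

A coupling assay on isolated mitochondria records OCR (pmol O₂/min) in
repeated measurement cycles ("ticks") through five injection phases:
substrate-only basal, ADP, oligomycin, FCCP, antimycin A. The
corresponding states are state 2, state 3, state 4o, state 3u and the
non-mitochondrial residual. An electron-flow protocol (FCCP-uncoupled
basal → complex inhibitor → complex substrate → antimycin →
TMPD/ascorbate) is handled by the same machinery with its own phase/state
map.

Extraction rules:

* **Second-basal rule.** The instrument's first basal measurement only
  verifies equilibration; state 2 is always the *second* basal tick.
  Fewer than two basal ticks is an error. We apply the same rule to the
  electron-flow assay's uncoupled basal, since the equilibration logic is
  the instrument's, not the protocol's.
* **Phase statistic.** Every other state is the *mean* of its phase's
  ticks by default (`phase_stat = "mean"`), because the assay reports one
  OCR value per measurement cycle and the mean is robust to a noisy
  cycle. `"last"` is available for plateau-seeking protocols; the two
  differ only when a phase drifts.
* **Replicate aggregation.** Technical replicate wells are averaged per
  animal *after* state extraction, so all downstream statistics run at
  n = animals. Averaging commutes with normalization when replicates
  share normalizers, which our tests verify.
* **Normalization.** Each well's states are divided by its relative
  protein load (`protein_ug / 2.5 µg` reference — kept total even when
  loading was equalized) and then by its citrate-synthase activity, the
  standard marker of mitochondrial content. The chain is recorded in the
  result and re-normalization is refused.
* **Residual correction.** Post-antimycin (non-mitochondrial) OCR is
  *not* subtracted by default — raw negative state-4o values are a
  real feature of these assays and the offset rule below handles them —
  but `antimycin_correct = TRUE` enables subtraction, recorded in
  metadata.

## Coupling thermodynamics

Oxidative phosphorylation is modeled as a two-flow linear energy
converter: an input flow (oxidation) drives an output flow
(phosphorylation) with degree of coupling q ∈ [0, 1]. State 4o isolates
the leak-dominated, zero-output flux; state 3 the phosphorylating flux.
This gives

* RCR = state 3 / state 4o,
* q = √(1 − state4o/state3)  (equal to √(1 − 1/RCR) at zero offset),
* η-opt = q² / (1 + √(1 − q²))², the efficiency at the
  optimal-efficiency force ratio x_opt = −q/(1 + √(1 − q²)).

**Offset rule.** Negative state-4o readings occur in practice (drift, or
over-subtraction when residual correction is enabled — the generator can
reproduce either mechanism via `drift_per_tick` or `state4o_shift`).
RCR then needs a positive range, so a single constant
c = −min(state4o) + ε is added to *all* state-3 and state-4o readings of
the batch; c = 0 when all state 4o are positive. ε defaults to 1% of the
median state 3 — small enough to leave positive batches essentially
untouched (RCR → state3/state4o as ε → 0), large enough to keep the
smallest adjusted state 4o away from zero. The applied c is always
reported. q is computed from the *offset-adjusted* states so that q and
RCR describe the same numbers.

**Clamping.** When state 4o > state 3 (RCR < 1, q undefined) the default
policy sets q = 0 with a per-sample flag so cohort statistics stay
computable; `q_policy = "strict"` errors instead. Ratios below 0 cannot
occur after the offset.

**Set points.** The four Stucki set points are the argmax over q of the
converter output functions Fₙ(q) = qⁿ·s/(1+s)ⁿ (s = √(1−q²)); n = 1
(net output flow), 2 (output power), 3 (economic flow = flow ×
efficiency), 4 (economic power). They are derived at run time by
bracketed scalar maximization (`stats::optimize`, default tolerance
1e-8, guarded by a bracket check and cached) rather than hard-coded;
the test suite compares them to a 10⁻⁶-step grid argmax and to their
printed three-decimal values 0.786, 0.910, 0.953, 0.972. Band
classification uses half-open intervals [lower, upper), so a q exactly
at a set point belongs to the band above it.

## Indirect calorimetry

Per 30-min bin: RER = VCO₂/VO₂; EE = VO₂/bw^0.75 in ml/min/g^0.75 —
the mass-exponent-normalized oxygen uptake itself, with no caloric
(Weir) conversion, because that is the unit the downstream comparisons
are made in. The body weight used in the exponent is each animal's mean
recorded weight over the window (configurable); whether lean or total
mass is more appropriate is a genuine open question in the field — total
is the default here.

Substrate oxidation uses the protein-free equations (VO₂, VCO₂ in
L/min, output g/min, reported as mg/min):

CHO = 4.585·VCO₂ − 3.2255·VO₂  FAO = 1.6946·VO₂ − 1.7012·VCO₂

The coefficients live in one constants table
(`mitothermics:::OXIDATION_COEF`). Their structure fixes two
physiological thresholds that the tests verify directly: CHO crosses
zero at RER = 3.2255/4.585 ≈ 0.7035 (pure fat oxidation, the "0.7
line") and FAO at RER = 1.6946/1.7012 ≈ 0.9961 (pure carbohydrate, the
"1.0 line"). Outside [0.7035, 0.9961] one rate goes negative —
physiologically meaningless, usually measurement noise at RER ≳ 1 — and
is clamped to zero with a per-bin flag; raw values are kept in
`cho_raw`/`fao_raw`. Bins with VO₂ = 0 are masked, never silently
dropped.

**Circadian window.** Summaries use exactly the first two complete
light/dark cycles (48 h = 96 bins at 30 min) starting at the first bin
at/after the configured light onset (ties at the exact onset belong to
light); anything recorded after the window is ignored, so extending a
trace never changes the summary. Phase means are reported per animal for
light, dark and the duration-weighted total; a phase-mean RER outside
[0.6, 1.3] triggers a warning. Intake metrics convert summed food mass
via the diet's energy density (kJ/g) to energy intake per gram body
weight and weight change per convertible energy (mg/kJ).

## Proteome and copy-number statistics

* **Differential abundance.** Two-sided Student t-tests run on log2
  abundances (the field norm for label-free intensities — the raw scale
  is available via `log_transform = FALSE`); the fold change is reported
  on the linear scale as the ratio of group geometric means. A protein
  is called at p < 0.05 (raw by default — BH-gating is available but
  volcano-style filtering conventionally gates on raw p) *and* fold
  ≥ 1.5 or ≤ 1/1.5. Zero-variance proteins are excluded with a reason
  code, not dropped silently.
* **EASE-style enrichment.** The "subtract one hit" penalty has two
  common readings; the default decrements the observed overlap inside
  the hypergeometric tail, p = P(X ≥ max(k−1, 0)), which reduces to the
  classical one-sided Fisher test when the penalty is disabled
  (`method = "fisher"`, verified exhaustively for all margins N ≤ 12)
  and is never anti-conservative relative to it. The alternative 2×2
  cell-decrement reading is available as `method = "decrement"`. BH FDR
  is applied across pathways.
* **Pathway z-scores.** Each protein is standardized across *all*
  samples pooled (the overall experimental mean), not per group — so
  over/under-representation is always relative to the whole experiment.
  The group contrast is the mean of per-protein differences in mean z,
  with a 95% t-interval using pathway member proteins as the unit of
  replication; singleton pathways get a flagged, undefined CI, and a
  degenerate all-equal difference vector yields a zero-width interval.
* **mtDNA ratio.** Replicate Ct values are averaged per animal per gene
  first; ratio = 2^(Ct_nuclear − Ct_mito). The ratio is reported
  relative (no diploidy factor): only group contrasts are interpreted,
  and adding any constant to all of an animal's Cts cancels.

## Test-selection machinery

Two-group comparisons gate on Shapiro–Wilk at α = 0.05 *per group*
(both must pass) before choosing Student's t-test (equal variances, per
the classical convention; Welch is a switch) over Mann–Whitney; the
exact Mann–Whitney distribution is used for small untied samples, the
tie-corrected normal approximation otherwise. Groups too small (n < 3)
or degenerate (zero variance) for the gate force the nonparametric
branch with a recorded reason. More than two groups use one-way ANOVA
with Tukey HSD. BH correction and Pearson R² with a zero-slope test
round out the toolbox.

## The synthetic-data generator

The generator exists so that every downstream stage has a testable
input with known truth. Its defaults *are* the study conditions the
package targets: 6 animals/group in technical triplicate on the plate
(5%, tick-level CV, plus a 5% between-animal CV per state); 72 h of
30-min cage bins beginning at 06:00 with 12 h/12 h phases; 1090
proteins, 5 samples/group, 73 up- and 13 down-regulated at 2-fold;
qPCR Ct triplicates from 5 animals/group with a 1.25× treated-group
ratio. Flux state means encode the programmed treatment effects
(state 3: −55% complex I, −56% complex II; state 2: −40%/−36%;
state 3u: −42%/−47%) and leak levels chosen so control complex-I
coupling sits above q_p, control complex-II below q_p, and treated
complex-II above q_p_ec. Cage targets are EE 7.2 vs 6.3
ml/min/g^0.75 (the difference carried by the dark phase) and 48-h RER
0.95 vs 0.89.

Functional forms (the measured data constrain only means, so these are
modeling choices): OCR ticks are phase mean + linear within-phase drift
+ Gaussian noise — an instantaneous step at each injection; circadian
VO₂ is a square-wave light/dark contrast modulated by a small 24-h
sinusoid, with VCO₂ = RER(t)·VO₂(t) and phase-dependent RER; abundances
are log-normal; Ct noise is Gaussian with a between-animal shift common
to both genes (which cancels in the ratio, as it should). Each
generator draws from its own RNG substream derived from (master seed,
generator name), so adding a generator never shifts another's draws,
and a fixed seed reproduces outputs bit-for-bit. Every generator
attaches a ground-truth sidecar (written as JSON by
`write_truth_sidecar()`); analysis code never reads sidecars — they
exist solely to score recovery.

One deliberate inconsistency is worth knowing: phase-level EE targets of
6–8 ml/min/g^0.75 at mouse body weight imply VO₂ of tens of ml/min,
which makes the absolute simulated CHO/FAO rates proportionally larger
than the ~1–2 mg/min seen in cage reports whose EE is on other unit
conventions. The EE unit is the contract here; RER, all contrasts and
all recovery statistics are unaffected, but absolute simulated oxidation
rates should not be read as physiological.

What the generator does *not* emulate: autocorrelated instrument drift,
well-position (edge) effects, missing-at-random dropouts in proteomics,
activity-driven feedback on VO₂, or any pharmacokinetics of the injected
compounds. Passing recovery tests therefore show the *analysis* is
correct and adequately powered under clean noise — not that real plates
or cages are free of the artifacts above.

## Problem sizes and numerical tolerances in the test suite

Recovery checks simulate 100 independent cohorts at the default study
scale (6/group × 3 replicates for plates; 12 animals × 144 bins for
cages); null-calibration checks use 100 seeds of 40-protein tables;
exhaustive enrichment identities cover all hypergeometric margins up to
N = 12. Set-point derivation is checked to 10⁻⁴ against a brute-force
grid and to ±0.001 against the three-decimal printed constants.
Pipeline determinism is asserted byte-for-byte on the emitted JSON/CSV.
These sizes keep the full suite comfortably within a coffee break on a
single core while leaving each stochastic assertion with a wide margin.

## Known limitations

* The q mapping uses state 4o as the converter's zero-output flow
  fraction; it reproduces the expected qualitative set-point structure,
  but per-animal numerical validation against published cohorts would
  require their raw plate data.
* No flow–force fitting (phenomenological conductances), membrane
  potential, or proton-leak kinetics — q and η-opt are state-ratio
  summaries, not mechanistic fits.
* Calorimetry offers no ANCOVA-style body-mass adjustment; EE is
  exponent-normalized only.
* GO/pathway membership must be supplied as GMT; no ontology access is
  bundled.
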