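---
title: "The bistable commitment switch of adipocyte differentiation: model, calibration and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bistable commitment switch of adipocyte differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposwitch)
```

## The model

Preadipocytes convert into lipid-accumulating adipocytes through an
all-or-none commitment decision. `adiposwitch` implements a six-variable ODE
model of the transcriptional circuit behind that decision. The state
variables are the transcription factors C/EBP&beta;, PPAR&gamma; and
C/EBP&alpha;, the insulin-pathway readout pAKT, the insulin receptor (IR),
and stored fat; all concentrations are relative units, normalized so that
each transcription factor's unstimulated steady state equals 1 under the
reference calibration.

The wiring (one equation per species, mass-action degradation everywhere):

* **C/EBP&beta;** is driven by the product of the glucocorticoid and cAMP
  inputs, plus a second-power Hill term in PPAR&gamma; *activity* — the
  PPAR&gamma;&rarr;C/EBP&beta; feedback ("loop 2").
* **PPAR&gamma;** is driven by a third-power Hill term in the *sum*
  C/EBP&beta;+C/EBP&alpha;, multiplicatively gated by pAKT saturation.
* **C/EBP&alpha;** is driven by a third-power Hill term in PPAR&gamma;
  activity (the PPAR&gamma;&harr;C/EBP&alpha; loop, "loop 1").
* **pAKT** is produced proportionally to insulin and to basal+IR abundance,
  and is suppressed by the product of the cAMP and glucocorticoid inputs —
  insulin signaling is de-repressed only after the induction cocktail is
  washed out.
* **IR** is induced by C/EBP&alpha; ("loop 3").
* **Fat** accumulates under joint saturable control of pAKT and PPAR&gamma;
  activity and turns over slowly.

Rosiglitazone is a PPAR&gamma; *ligand*: it multiplies PPAR&gamma; activity
by a saturable boost `1 + rosi_gain * d/(rosi_k + d)` without adding protein
(`pparg_activity()`). Doses are expressed in units of `rosi_k`
(dose 1 = half-saturating); the reference set fixes `rosi_k = 1`.

Two printed-form ambiguities are resolved as documented switches:

* the C/EBP&alpha; denominator exponent is matched to its numerator
  (`alpha4^3`); `alpha4_printed = TRUE` restores the mismatched squared
  form;
* insulin enters as an external channel `u_ins` in `[0, 1]` multiplying
  pAKT synthesis, while IR remains a dynamic variable. The no-insulin
  control is `protocol_dim(insulin_after = FALSE)`.

siRNA perturbations are modeled as constant multiplicative scaling of the
target's whole synthesis term (`apply_knockdown()`); a glucocorticoid-
receptor knockdown scales the GR input channel instead.

## Why three consecutive loops

At constant inputs every species is, at steady state, an explicit function
of PPAR&gamma; alone, so the fixed points of the full system are the
crossings of a scalar map (`find_fixed_points()` exploits this exactly).
Under the reference calibration the intact circuit has two stable states —
basal (PPAR&gamma; = 1) and differentiated (PPAR&gamma; about six-fold
higher) — separated by a saddle. Removing loop 2 (the
PPAR&gamma;&rarr;C/EBP&beta; term) collapses the structure to a single low
state: one loop does not supply enough effective cooperativity, which is
the circuit-level argument for the consecutive-loop design. Loop 3 is
dispensable for bistability but boosts the committed state: with it intact
the deterministic cell roughly doubles its PPAR&gamma; between 48 h and
72 h of the standard protocol, because washout of the cocktail also
de-represses insulin signaling.

## Stochastic population model

Cell-to-cell variability is *extrinsic*: each simulated cell draws, once,
median-preserving lognormal factors (`sigma = sqrt(log(1+cv^2))`) for the
synthesis, degradation and basal parameters of the C/EBP&beta;, PPAR&gamma;
and C/EBP&alpha; groups, then evolves deterministically from the basal
fixed point of its own parameter set. Default CVs are 15% for the
PPAR&gamma; group and 30% for the two C/EBP groups; the insulin-pathway and
fat groups are unvaried by default (the evidence for varying them is
weaker, and the headline behaviors do not require it). Draws are taken in
a fixed parameter order from one seed, so a `run_population()` table is
bit-reproducible; all randomness in the package flows through explicit
seed arguments.

With this noise model a uniform 48-h induction splits the population:
cells whose sampled parameters put them below the commitment boundary
revert on washout, the rest lock in, and the end-state PPAR&gamma;
distribution is bimodal. `noise_window_scan()` scales all group CVs
together (preserving the 15/30 ratio) and reports the window in which
bimodality coexists with intact bistability. The intactness rule — at most
5% of cells stranded between twice the basal reference and half the high
reference — is this package's concrete rendering of "bistability breaks";
the classifier itself (below) decides bimodality.

What the generator does *not* emulate: intrinsic (temporal) noise, cell
division and crowding, measurement background in the readouts (that part is
exercised separately by the imaging module). Passing tests therefore show
that the circuit logic reproduces the population phenomenology, not that
real micrographs would quantify identically.

## Bimodality classification

`classify_bimodality()` fits one- and two-component Gaussian mixtures to
log10 intensities (mclust, unequal variances) and calls a distribution
bimodal when BIC prefers two components, both weights are &ge; 5%, and the
means separate by &ge; 2 pooled SDs; the threshold is the equal-posterior
crossing. These rules are a concrete substitute for calling visibly
separated histogram peaks by eye, and the weight floor deliberately treats
sub-5% shoulders as unimodal. `fraction_differentiated()` uses this
threshold, falling back to a supplied fixed threshold (by convention the
log-midpoint of the two deterministic fixed points) when a distribution is
single-peaked, e.g. at saturating stimulus.

Predictiveness of pre-switch expression is scored by the exact rank AUC;
the graded insulin&rarr;fat relation is checked by Spearman correlations
within the high-PPAR&gamma; subpopulation plus per-pAKT-decile unimodality
of fat.

## Dose-response conventions

`fit_hill()` is a 4-parameter Levenberg–Marquardt fit, multi-started over
Hill exponents. `dose_response()` titrates one input channel from the
basal state in a 12-point 2-fold dilution series and offers two readouts:

* `mode = "timed"` (default, 48 h): the endpoint-fixed titration used by
  immunostaining experiments. This is the mode behind the reported
  cooperativity (Hill &asymp; 2.5 across the three factors) and the
  &asymp; 4-fold EC50 separation between C/EBP&beta; and C/EBP&alpha; —
  the commitment kinetics (tens of hours even at saturating dose) smear
  the underlying fold into a graded sigmoid, exactly as in a 48-h
  experiment.
* `mode = "steady_state"` (&ge; 240 h per dose): the forward-branch
  attractor. In the bistable regime this branch jumps at the fold, so a
  Hill fit to it describes the branch, not molecular cooperativity; the
  curve's metadata says so. This asymmetry is why the package computes the
  headline Hill numbers from the timed mode.

The floor of the Hill fit is left free (whether the original fits pinned
it at basal is unknowable from the text).

## Steady-state analyses

`stimulus_sweep_hysteresis()` is naive warm-started continuation: adequate
for one-parameter S-shaped diagrams and easy to verify against
`find_fixed_points()`; no arclength continuation, codimension-2 analysis or
limit-cycle detection is attempted. Relaxation is 500 h per level; the
bistable window is where forward and backward branches differ by >10%.
`nullclines_one_loop()` clamps pAKT (default: its insulin-on low-state
value — the paper-style single-loop picture leaves the clamp unspecified)
and draws both nullclines in closed form for a series of constant
C/EBP&beta; levels.

Numerical choices throughout: `lsoda` with rtol 1e-8 / atol 1e-10 and hard
restarts at protocol breakpoints; negative overshoot beyond the absolute
tolerance is an error, smaller overshoot is clipped to zero; fixed points
verified to residual &le; 1e-8 and de-duplicated at 1e-4 relative
distance; Jacobians by central finite differences.

## Synthetic imaging

`generate_field()` renders simulated cells into six 16-bit channels:
nuclear stains as uniform disks (Gaussian-blurred; blur preserves
integrated signal, which keeps per-cell totals proportional to the state),
cytosolic stains on the perinuclear annulus, plus background, optional
linear gradient, Poisson shot noise and Gaussian read noise. The default
pixel size of 1.6 &micro;m/px is a plausible calibration for a 4&times;
objective with a ~1.3-Mpx CCD (the true calibration is not recoverable
from the text) and is configurable. Quantification mirrors the measurement
procedure: Hoechst centroids by smoothed local maxima (the original
detector's internals are undescribed; this is a documented substitute),
region growth to 30% of the *per-nucleus* peak (robust to bright
neighbors), 7-&micro;m dilation for the cell mask, local background as the
median of a 2–5 &micro;m annulus excluding all cells, nuclear channels
measured on the nucleus mask and cytosolic channels on the cell mask.
Closely packed nuclei may merge into one detection; tests place nuclei at
a minimum separation so that recall/precision &ge; 0.95 is meaningful.

## Calibration and the reference parameter set

The model's rate constants are not published, so the package ships a
reference set (`inst/extdata/reference_params.json`, loaded by
`reference_params()`) produced with the package's own calibration
machinery. Hard qualitative gates came first: genuine two-stable-state
structure at zero stimulus (checked on the exact scalar reduction — a
600-h relaxation can be fooled by a saddle-node ghost that decays on the
thousand-hour scale), one-loop monostability, durable commitment after
48-h induction, reversion without loop 2. Quantitative targets were then
scored: Hill &asymp; 2.5 and EC50 ratio &asymp; 4 (48-h titration), a
&asymp; 2-fold PPAR&gamma; rise between 48 h and 72 h, commitment in
roughly a day under saturating activation, a 15–45% CV bimodality window,
a &asymp; 16-fold conversion dose range, &asymp; 3-fold fat contrast and
&asymp; 50% lock-in after a 24-h saturating pulse. `calibrate_params()`
exposes the same bounded log-space multistart + Nelder–Mead machinery for
user-defined targets; `reference_calibration_targets()` records the
numeric targets and tolerances used. Many parameter sets satisfy these
targets — the shipped set is a convention, not an estimate of any "true"
values.

Problem sizes: the test suite runs its stochastic checks at 150–400 cells
per condition, sizes at which binomial noise is comfortably inside the
tolerances being checked; `scripts/acceptance.R` recomputes everything at
1,000 cells per condition.

## Known limitations

* The lumped ODEs contain no transcription/translation detail, delays or
  space; "day N" is exactly 24N hours.
* Extrinsic noise only; no division, movement, or contact effects.
* The insulin channel is binary in the shipped protocols; no
  dexamethasone/IBMX pharmacology, and rosiglitazone doses are not mapped
  to molar concentrations.
* The no-insulin control (`insulin_after = FALSE`) silences pAKT entirely,
  which blocks the switch in this model; biologically, serum supplies
  residual insulin-like signaling, so this control is best read as the
  extreme case.
* Calibration is a point estimate with known non-identifiability.
* Under the prescribed 30% lognormal parameter noise, a minority of
  simulated cells (roughly a tenth) lose bistability altogether: some can
  never commit even at saturating activation, a few commit without any
  stimulus. Because of this, the conversion-fraction dose curve spans
  roughly 7% to 90% rather than 0% to 100%, the no-conversion/full-
  conversion dose range is not attained on the default grid, and the
  parameter-noise bimodality window (bimodal *and* at most 5% of cells
  stranded between the reference states at 96 h) comes out empty at the
  shipped calibration -- the scan reports its per-CV diagnostics instead.
  Shrinking this broken-cell tail while holding the paper-matched
  cooperativity, thresholds and kinetics is the main open calibration
  problem; the ensemble machinery itself is agnostic to the parameter set.
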