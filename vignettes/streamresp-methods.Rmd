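---
title: "Methods: from oxygen traces to thermal risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to thermal risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamresp)
```

`streamresp` implements a complete analysis chain for stream-side
intermittent-flow respirometry: raw dissolved-oxygen logs in, per-fish
metabolic traits and per-watershed thermal-risk metrics out. This
vignette explains the models and conventions behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open.

## The measurement model

An intermittent-flow trial alternates a closed measurement phase (the
chamber is sealed and the fish depletes oxygen) with an open flush phase
(fresh water replaces the chamber volume). The default cycle is 6 min
measurement + 4 min flush, so an 18–24 h overnight trial yields 108–144
measurement phases. Each phase contributes one oxygen consumption value
via the mass-specific rate equation

$$\dot{M}O_2 = \frac{\Delta[O_2]_{fish}\,(V_{chamber} - M)
  - \Delta[O_2]_{background}\,V_{chamber}}{M},$$

where the $\Delta[O_2]$ terms are least-squares depletion slopes
(mg O$_2$ L$^{-1}$ min$^{-1}$), $V_{chamber}$ is chamber volume (L), and
$M$ is body mass (kg), which also stands in for the fish's displaced
volume at density 1. Written on a single line, the operator precedence of this expression is
ambiguous; the reading adopted here divides the entire bracketed difference by mass, which is the standard
respirometry form and the only one that yields mass-specific units.

Background respiration (microbial activity in tubing and chambers) is
measured in the empty respirometer before and after the trial. The two
slopes are interpolated linearly in time by default (`"constant"` uses
their mean); negative evaluations — possible with probe noise — clamp to
zero. A subtlety the simulator makes explicit: microbes consume oxygen at
a mass rate, so the *concentration* slope they produce in a fish-occupied
chamber is larger than in the empty chamber by $V/(V-M)$; the rate
equation's $\Delta[O_2]_{background} \cdot V_{chamber}$ term is exactly
the correction that removes the microbial mass rate.

Numerical conventions: windows are half-open $[start, end)$ on a
0-based seconds clock; a trailing partial cycle is dropped; windows with
fewer than 3 samples are excluded; `trim_s` (default 0, configurable)
can discard a mixing transient at the start of each phase; an $r^2$
floor for window quality is available but disabled by default — no
window is silently discarded unless the analyst asks for it.

## Traits

- **SMR** is the mean of the lowest 20% of all per-cycle values, the
  count being $\max(1, \mathrm{round}(0.2N))$ with half-up rounding
  (field protocols rarely state a rounding rule; half-up is the
  deterministic choice). All recorded values enter, including the recovery period —
  the protocol applied this uniformly, and post-recovery MO$_2$ is
  empirically stable even under fluctuating temperature. The
  temperatures of the selected cycles are averaged to give SMR's
  temperature.
- **MMR** is the maximum per-cycle value. With an exhaustive 3-min chase
  and 30-s air exposure immediately before the trial, this is normally
  the first cycle. Because a 6-min window averages the decaying
  post-exercise excess, the first-cycle MO$_2$ underestimates the
  instantaneous peak — an inherent property of chase-protocol MMR at
  this cycle length, and the reason recovery tolerances below are stated
  in cycle units.
- **AAS** $= MMR - SMR$ and **FAS** $= MMR/SMR$ follow directly; the
  identity $AAS = SMR\,(FAS - 1)$ is enforced by construction and tested.
- **RMR** averages post-EPOC values within 1 °C temperature bins centred
  on integers (bin width configurable; a diurnal Ambient trial
  typically spans 3–5 distinct bins per watershed). Bins with fewer
  than 3 measurements for a fish are dropped.
- **Q10** $=(R_2/R_1)^{10/(T_2-T_1)}$. For group-level reporting the
  package compares watershed-mean rates at the lowest Ambient
  temperature and the Climate treatment temperature.
- **Fulton's K** $=10^5 M/L^3$ (g, mm) summarises condition, and the
  allometric check regresses $\ln$ whole-animal rate on $\ln$ mass. The
  criterion for "no mass correction needed" is a 95% CI containing 1 —
  the isometry of the mass-specific formulation. Published analyses often assert this
  conclusion without stating a criterion; this one is the package's own,
  explicit and inspectable via the returned CI.

## Recovery kinetics

A smoothing spline (`stats::smooth.spline`) is fitted through the MO$_2$
series; by default the smoothing parameter is chosen by generalized
cross-validation and recorded in the output for reproducibility, since
smoother settings are rarely reported yet shift the detected times. Two thresholds are
then located on the fitted curve, both on a clock starting at the MMR
cycle: 50% of MMR (short-term recovery, `Time[MMR50]`) and 20% above SMR
(end of EPOC). Crossing detection evaluates the curve on a 1-s grid and
refines the first downward crossing by bisection; a curve already below
the threshold gives 0 and one that never crosses carries a
`crossed = FALSE` flag. First-crossing semantics mean later noise-driven
re-crossings are ignored, matching the notion of a single recovery
duration. When $0.5\,MMR \le 1.2\,SMR$ the two thresholds lose their
ordering and the result carries a `thresholds_overlap` flag; a curve
pinned at SMR therefore reports EPOC complete at 0 min but `Time[MMR50]`
as not-crossed, which is the geometrically faithful answer.

On noiseless exponential recoveries the detected times match analytic
crossings to well within one 10-min cycle; that cycle length — not the
spline — is the resolution limit of the method.

## Thermal risk

**TSM** subtracts a site's MWMT (maximum weekly maximum temperature,
from stream-network temperature modelling; baseline 2002–2011 and 2080
projections ship in `site_context()`) from CT-max. Group TSM is the mean
of per-fish TSMs, which equals mean CT-max minus the single site MWMT.

**T_pejus** is operationalised as the temperature at which FAS falls to
3 — the level at which a subadult salmonid can still digest a meal and
retain scope for activity — obtained by inverting a least-squares line
fitted to per-fish (mean trial temperature, FAS) points pooled across
treatments *within a watershed*. Per-fish fits are not attempted: each
fish experiences one treatment, so the temperature contrast only exists
at the watershed level. A non-negative fitted slope (FAS stable or
rising) leaves T_pejus undefined rather than extrapolating to an
absurd crossing; a defined crossing outside the observed temperature
range carries an extrapolation flag. The threshold is configurable
(`fas_threshold`), as different species and life stages warrant
different criteria. **WT** $= T_{pejus} - MWMT$, with undefined values
propagating.

CT-max processing reads the loss-of-equilibrium temperature off the
recorded heating ramp (nominally 0.3 °C/min) and reports realised
heating rates per 3-min window, mirroring how field ramps are quality
checked.

## Group statistics

Kruskal–Wallis (midranks, tie-corrected, $\chi^2$ reference), Dunn's
post hoc z-tests and one-way ANOVA are implemented from first principles
— they are part of this package's contract — and are validated in the
test suite against independent implementations
(`stats::kruskal.test`, `stats::aov`, a brute-force midrank oracle) and
by simulated type-I error at $\alpha = 0.05$. Conventions for degenerate
input: an all-constant sample gives $H = 0, p = 1$ (the tie-correction
denominator vanishes); zero within-group variance gives $F = 0$ for
equal means and $F = \infty$ for unequal ones. Dunn p-values are
unadjusted by default; Bonferroni and Holm adjustments are offered. The RMR–temperature relationship is
fitted as $\ln(RMR) = b\,T + a_{watershed} + \varepsilon$ by ordinary
least squares. A full treatment would use a mixed model with random
treatment and fish intercepts; the fixed-effects approximation recovers the
inferential targets (slope sign and magnitude, watershed offsets) at
this design scale, and the per-fish random-intercept robustness of the
slope is checked by simulation in the tests.

## The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions everything else is validated under:

- **Trial structure**: 2-L chambers, 6 + 4 min cycles, trial durations
  drawn uniformly from 18–24 whole hours, probe sampling at 1 Hz (1 Hz is
  typical of fibre-optic oxygen meters).
- **Physiology**: instantaneous
  $\dot{M}O_2(t) = SMR_{ref}\,Q_{10}^{(T(t)-T_{ref})/10}
  + E_0 e^{-kt}$ — SMR scaled to the current temperature plus an
  exponentially decaying post-exercise excess. Chamber oxygen integrates
  this through the rate equation; flushing relaxes oxygen exponentially
  toward a fixed 9.0 mg/L air-saturation ceiling with a 1-min time
  constant (effectively complete in a 4-min flush). Full
  temperature–solubility coupling is deliberately out of scope.
- **Noise**: Gaussian probe noise (default sd 0.02 mg/L) on recorded
  samples only; background respiration at a per-watershed fraction drawn
  from 0.15–2.1% of fish respiration, the observed field range.
- **Temperature**: Ambient treatments get a sinusoidal diurnal cycle
  (half-range defaults 1.2–1.95 °C across watersheds, peak at 16:45,
  trials starting at 09:30); Max and Climate treatments are constant.
- **Cohort**: 8 fish × 3 treatments × 4 watersheds; fork lengths
  ~N(130, 12) mm clipped to the observed 100–181 mm range and condition
  factors ~N(1.00, 0.04) clipped to [0.90, 1.16], so generated K values
  centre on 1.00 with ≥95% inside the observed 0.93–1.13 band; CT-max
  for Ambient-treatment fish from truncated normal distributions.
- **Determinism**: one root seed; every per-fish stream derives from
  (root seed, fish id), so cohorts are reproducible fish-by-fish.

Per-watershed defaults (SMR at the site's ambient mean, Q10, EPOC
magnitude and decay, CT-max mean/sd) were chosen once from the published
group-level summaries for the four Oregon watersheds — e.g. Q10 values
of 3.25/2.02/1.17/2.01 and CT-max means recovered from printed mean TSMs
plus the site MWMTs — so that simulated cohorts reproduce the qualitative
regimes: a steep FAS decline with warming in the N. Santiam, near-stable
FAS in the McKenzie (leaving T_pejus undefined or heavily extrapolated),
the Siletz as the warm-adapted high-CT-max site, and watershed-mean
`Time[MMR50]` in the 10–24 min range.

What the generator does **not** emulate — and hence what passing tests
cannot certify about field data: probe drift and calibration error,
within-chamber mixing dynamics, activity cycles and spontaneous
swimming (MO$_2$ noise beyond the probe), digestion, oxygen solubility
varying with temperature, and non-exponential recovery shapes. Tests on
synthetic data demonstrate that the *estimators* are correct under the
stated generative model, not that the model captures every field
artefact.

## Problem sizes and runtime choices

The test suite and acceptance script favour short trials (1–6 h), coarse
probe sampling (5 s) where only cycle structure matters, 1 Hz where
slope precision matters, Monte-Carlo sizes of 200–5000 replicates per
property, and one full 96-fish cohort at 1 Hz for the end-to-end run.
These sizes give stable statistics while keeping a complete run in the
tens of seconds on a single core.

## Known limitations

- SMR via the lowest-20% rule is simple and standard for field data,
  but quantile/mixture estimators can be less biased at low cycle
  counts; they are out of scope here.
- T_pejus inherits the linearity assumption of the FAS–temperature fit;
  with only three treatment temperatures per watershed, curvature cannot
  be diagnosed.
- The fixed-effects RMR model understates uncertainty relative to the
  mixed model it approximates; its standard errors should not be used
  for inference about watershed differences.
- EPOC magnitude (the area under the recovery curve) is not computed;
  only durations are.
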