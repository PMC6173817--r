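---
title: "Traffic-light vital signs alerting: models, thresholds and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traffic-light vital signs alerting: models, thresholds and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsalert)
```

## The problem

Obstetric haemorrhage, hypertensive disorders and sepsis account for the
majority of preventable maternal deaths, and each announces itself through
blood pressure and pulse abnormalities well before the crisis. In
low-resource maternity settings the people taking those measurements are
often minimally trained, so an alerting rule has to be computable on the
device and readable at a glance. The traffic-light early warning system
implemented here does exactly that: every reading maps to green, yellow or
red, with a display symbol distinguishing the two conditions that drive
the alert.

`vsalert` packages that classification engine together with the two kinds
of statistics a device programme needs around it: paired
device-versus-reference validation statistics (is the measurement itself
accurate?) and threshold-versus-outcome evaluation (do the alert tiers
actually stratify clinical risk?), plus seed-controlled generators that
simulate all of the above for testing and calibration.

## The classification model

Two marker–threshold pairs drive the alert:

* **Hypertension.** A reading is yellow when SBP $\ge$ 140 or DBP $\ge$ 90
  mm Hg, red when SBP $\ge$ 160 or DBP $\ge$ 110 mm Hg. Pulse plays no
  role here. These are the conventional obstetric treatment and severity
  thresholds (pre-eclampsia surveillance at 140/90, severe hypertension at
  160/110).
* **Shock.** The Shock Index $SI = \text{pulse} / \text{SBP}$
  (dimensionless; normal range in pregnancy roughly 0.7–0.9) is compared
  against $SI \ge 0.9$ for yellow and $SI \ge 1.7$ for red. SI rises early
  in haemorrhage and sepsis, before either pulse or pressure alone looks
  alarming.

The alert colour is the more severe of the two tiers. The alerting
*condition* is prioritised differently: shock, which generally needs the
more urgent response, wins whenever the shock tier is at least yellow, and
its display symbol (a flashing down arrow) signals higher urgency than the
hypertension symbol (a constant up arrow). Both component tiers are kept
in the result, so the prioritisation never destroys information. Where a
reading is shock-yellow *and* hypertension-red, the colour is red and the
single display is the shock arrow — the device has one symbol slot, and
the more urgent condition owns it; a consumer wanting both can read the
component tiers.

Numeric thresholds are configuration, not code (`vsa_thresholds()`,
`load_threshold_config()`), so a revised threshold set slots in without
touching the engine. Boundary handling is likewise explicit: the default
is inclusive (a reading exactly at 140/90 is yellow, matching how the
thresholds are quoted clinically), with a strict mode exposed because
published threshold tables rarely say which convention they intend.
Classification always uses the unrounded SI ratio; rounding (banker's, 2
decimals) is applied only by `si_display()`, so no reading can change tier
through formatting.

Readings are screened before classification (`validate_readings()`)
against plausibility windows — SBP 40–300, DBP 20–200 mm Hg, pulse 20–250
beats/min, SBP > DBP — and failures are reported row-wise with reason
codes rather than aborting a file ingest: in field use a transcription
error in one row must not silence the other alerts. Device utility states
(low battery, error) exist only as display-map entries; they were
deliberately kept out of the classification logic, as was a separate
"shock" light colour, which field testing of such devices showed users did
not understand.

## Device-validation statistics

The accuracy analysis follows the established paired-difference
methodology for sphygmomanometer validation. Sequential same-arm protocols
alternate reference (mercury/auscultatory) and device measurements,
seven per subject by default. Because true pressure drifts over the
session, the standard pairing compares each device measurement with the
*mean of the two flanking reference measurements* (`flanking_mean`,
giving 3 pairs from a 7-measurement sequence); `same_index` pairing
(device $k$ versus the immediately preceding reference) is provided for
sensitivity analysis and is the natural reduction for simultaneous
two-measurement designs. On a constant reference sequence the two schemes
coincide.

From the pairs, `difference_stats()` reports the arithmetic mean and
sample SD ($n-1$) of device-minus-reference differences per component.
Two verdicts are layered on top:

* **ISO criterion** (`iso_assess()`): pass iff $|\text{mean}| \le 5$ and
  $\text{SD} \le 8$ mm Hg, boundaries inclusive, for both components. The
  bound is applied to the absolute mean — the criterion is quoted
  sign-free, and an underestimating device is no safer than an
  overestimating one.
* **BHS grading** (`bhs_grade()`): cumulative percentages of absolute
  differences within 5/10/15 mm Hg against a grade table, A = 60/85/95,
  B = 50/75/90, C = 40/65/85, else D. The table ships as data
  (`bhs_grade_table()`), with these defaults transcribed from the BHS
  protocol, so an adapted protocol can supply its own.

`run_validation()` composes the pipeline overall and within
arm-circumference strata (closed bands 22–32 and 33–42 cm by default),
because cuff-fit bias is an arm-size effect: an oversized or "wide-range"
cuff can pass overall while failing badly in large arms.

## Cohort evaluation

`tier_outcome_table()` classifies a cohort and tabulates alert colour
against a named binary outcome; `tier_risk_metrics()` reports per-tier
risk, risk ratios versus green and a monotone-trend flag (risk
non-decreasing green → yellow → red, the signature of a well-calibrated
threshold set); `diagnostic_metrics()` collapses to a 2×2 at
"yellow-or-worse" (default, the screening question) or "red" and reports
sensitivity, specificity, predictive values and likelihood ratios, with
zero-denominator metrics returned as explicit `NA`s.

For pre/post intervention comparisons, `odds_ratio()` implements the
crude estimator $ad/bc$ with the Woolf (log-normal) 95% interval
$\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ and a normal-approximation
p-value. The Woolf form was chosen because field studies of this kind
report Wald-style intervals; exact/conditional intervals and adjusted or
cluster-aware models are deliberately out of scope, and the estimator is
documented as crude — published adjusted estimates will generally differ
from it (reconstructing one such comparison from its printed proportions
gives a crude OR of 0.604 where the adjusted publication figure is 0.58;
the package does not force agreement). The Haldane–Anscombe 0.5
correction for zero cells is opt-in and flagged in the result.

## What the generators emulate

All generators hang off one integer seed through a deterministic seed
tree (stream-named sub-seeds), so each generator is independently
reproducible and generating one dataset never perturbs another.

* `generate_population()`: a three-class mixture — normotensive
  (SBP 115(10), DBP 72(8), pulse 82(10)), hypertensive (155(15), 100(10),
  85(10)) and shocked (90(12), 55(10), 125(15); low pressure with marked
  tachycardia). Class weights default to 0.75/0.20/0.05. Pressures are
  correlated (SBP–DBP $\rho = 0.7$), truncated to the plausibility
  windows, and rounded to whole units as a device would report them. The
  normotensive and hypertensive parameters reflect typical obstetric
  distributions; the shocked class is *illustrative* — no published
  population model fixes it — and is documented as such.
* `generate_paired_study()`: 52 subjects by default, 26 per arm band,
  seven alternating measurements each. Device = truth + arm-band bias +
  N(0, error SD); reference = truth + N(0, `ref_sd`). The default bias
  structure (+1 mm Hg small arms, +8 mm Hg large arms, error SD 4)
  emulates a cuff that overestimates in large arm circumferences strongly
  enough to fail the ISO mean bound in that stratum while the small-arm
  stratum passes. Setting `ref_sd = 0` and per-component bias/SD turns
  the same generator into an exact replication of a simultaneous
  auscultatory-versus-oscillometric comparison (255 pairs, differences
  Normal(2.2, 6.1²) systolic and Normal(2.3, 5.2²) diastolic), which is
  what `scripts/acceptance.R` recomputes.
* `generate_outcome_cohort()`: realises designed tier proportions
  (default 0.70/0.20/0.10) *exactly* (largest-remainder apportionment) by
  rejection sampling from tier-targeted proposal distributions — every
  candidate is re-classified against the supplied threshold
  configuration, so the proposals affect efficiency only, never
  correctness; an unrealisable design errors after a bounded number of
  batches instead of looping. Outcomes are Bernoulli at designed per-tier
  risks (default 0.02/0.10/0.30, the kind of gradient a strongly
  predictive threshold set produces).
* `generate_prepost()`: Bernoulli indicator draws at designed per-phase
  proportions (defaults 25.1% of 694 pre, 16.9% of 547 post, an implied
  odds ratio near 0.60).

What passing tests on these data do **not** show: real vital signs are
serially correlated within a woman, gestational age shifts the
distributions, measurement rounding is digit-preferenced in auscultatory
practice, and adverse outcomes cluster by condition and site. None of
that is modelled, so simulation results here validate the *statistical
machinery*, not clinical performance.

## Numerical choices and problem sizes

Truncated-normal draws use batched rejection (acceptance near 1 at these
parameters); the SBP > DBP constraint is enforced after rounding, on the
values actually emitted. Ties at thresholds are governed solely by the
`inclusive_boundaries` flag. Empty strata and zero-denominator ratios are
explicit (`n_pairs = 0`, `NA`) rather than silent zeros.

The test suite exercises the classifier exhaustively on the integer grid
SBP 60–220, DBP 30–min(SBP−1, 140), pulse 30–180 (≈2.2 million
combinations) against an independently coded rule table; risk-recovery
properties use 200 seeded cohorts of n = 3000 and the interval-coverage
property 2000 simulated 2×2 tables — sizes chosen to make the Monte-Carlo
bands (3 binomial SEs; 95% ± 2% coverage) decisive while keeping a full
run comfortable on a laptop.

## Known limitations

* The classifier encodes the published threshold structure; it does not
  adapt thresholds by context (antenatal versus postnatal), since no
  context-specific thresholds are published for this display.
* Only the two pairing schemes above are implemented; Y-connector
  simultaneous-observer protocols and observer-training clauses of the
  formal validation standards are out of scope.
* The odds-ratio machinery is crude by design; confounding and clustered
  sampling must be handled upstream.
* The generators draw i.i.d. readings; they cannot be used to study
  longitudinal alerting behaviour.
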