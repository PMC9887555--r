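---
title: "Urgency of surgical delay: model, elicitation and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urgency of surgical delay: model, elicitation and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgprio)
```

## The decision problem

When surgical capacity is scarce, postponing procedure A for a month to
schedule procedure B is a trade in expected population health. `surgprio`
quantifies each side of that trade as the expected health loss per month
of delay — DALYs per month — for an average patient awaiting each
procedure, and ranks procedures by it. Because the quality-of-life (QoL)
inputs to that model come from expert panels and are the most
context-dependent ingredient, the package pairs the model with a
validation battery that asks: *if a different panel had supplied the QoL
weights, would the priorities change?*

## The cohort state-transition model

Three states — preoperative, postoperative, dead — advance in monthly
cycles from the patient's age at indication (`age0`) to a hard cap at
age 100 (the support of the life table), or until the living fraction
falls below `1e-9`.

* Waiting (cycles before the scheduled delay `d`): monthly death
  probability `1 - (1 - p_wait_death) * (1 - p_bg(age))`, i.e.
  independent competing risks of disease-related waiting death and
  background mortality.
* Surgery (start of cycle `d`): a fraction `p_periop_death` of survivors
  dies on the table; the rest enter the postoperative state in the same
  cycle.
* Operated: background and post-surgery excess hazards add on the
  log-survival (hazard) scale, `1 - exp(-(h_bg + h_excess))`, the
  standard competing-hazard approximation at monthly resolution. The
  excess hazard is recovered from the long-term survival fraction
  `s_long` over `horizon_years` (default 5) as
  `-log(s_long) / (12 * horizon_years)`.

QALYs accrue per cycle from cycle-start occupancy,
`(preop * q_pre + postop * q_post) / 12`. Discounting and half-cycle
correction are available (`model_settings()`) but default to off; the
urgency measure is a *difference* of two nearly parallel trajectories
one month apart, so both corrections largely cancel in it. The urgency
itself is `daly_per_month()`: the QALY difference between immediate and
delayed surgery divided by the delay (default one month; for longer
delays the per-month average).

Parameter uncertainty propagates through `run_psa()`: every uncertain
parameter (the two utilities and the three probabilities) is drawn from
a Beta distribution matched to its mean and SE by the method of moments
(a zero SE pins the parameter), the model is rerun per draw, and the
2.5/97.5 percentiles form the interval. Draws are fully determined by
the seed; an SE too large for its mean (`se^2 >= m(1-m)`) raises an
error naming the parameter rather than silently truncating.

## Elicitation and aggregation

Experts score health-state descriptions on a visual analogue scale from
0 (worst imaginable health) to 100 (best imaginable), calibrated with
published disability-weight anchor states; utilities are scores divided
by 100, and published disability weights enter as `1 - dw`. Between
Delphi rounds the panel sees the median and interquartile range
(`round_summary()`; quantile type 7, the linear-interpolation default of
most statistical environments — the convention matters only for small
panels). The panel's estimate for a procedure/state is the **mean of the
final-round individual scores**; the between-expert SD is reported as
the consensus measure. We use the mean of final individual scores rather
than a negotiated consensus value because per-procedure SDs are
meaningful only under that reading. Confidence intervals use the t
distribution — with panels of 15-18 the difference from the normal is
material — and are truncated to [0, 1].

Pooling two panels (`pool_panels()`) concatenates the individual expert
scores, weighting each expert equally; an alternative weighting each
*panel* equally (average of panel means) is available via
`method = "panel_means"`. Equal-expert pooling is the default because
"the estimates of both studies" most naturally means all elicited
values.

## The validation battery

* `bland_altman()`: differences are validation minus original per
  procedure/state; bias, `bias ± 1.96 * sd` limits of agreement, and the
  observed extreme differences. We report observed extremes for the
  "largest expected difference" item; a prediction interval is the other
  defensible reading, and the LoA already serve that role.
* `fit_random_intercept_model()`: REML fit of
  `response ~ study + state + (1 | procedure)` through `lme4::lmer`,
  study coded original = 0 / validation = 1, state pre = 0 / post = 1.
  With individual final-round utilities as response the study
  coefficient is the standardized mean difference between panels; with
  per-(study, state, procedure) SDs it is the consensus difference.
  There is no expert random effect — expert identity is nested within
  study and absorbed into the residual — and fixed-effect CIs use the
  normal approximation. A singular random-intercept variance (common in
  the SD model, where procedure-level variation in consensus is tiny) is
  reported, not treated as failure; genuine non-convergence sets
  `converged = FALSE` with a warning, never a silent fallback.
* `residual_diagnostics()`: residuals vs fitted, normal-quantile pairs,
  Shapiro-Wilk, and a scale-location slope (regression of
  `sqrt(|standardized residual|)` on fitted values) as the
  homoscedasticity indicator. Residuals at floating-point noise level
  are treated as a perfect fit (slope 0, normality test flagged
  unavailable).
* `compare_rankings()`: rank 1 is the most urgent procedure; ties get
  average ranks (and id-order for display, so output is deterministic);
  Spearman's rho is the Pearson correlation of the rank vectors, which
  handles ties correctly.

Consensus SDs are analysed on the utility scale by default (`sd_scale`);
the VAS scale is one flag away, since elicitation protocols report
either.

GBD-derived procedures — those whose weights come from published
disability weights rather than panels — are *excluded* from the
Bland-Altman and mixed-model comparisons (both panels share those fixed
weights, so they carry no between-panel information and would dilute the
study coefficient toward zero) and *included* in the rankings, which is
where they participate in practice.

## What the synthetic-data generator emulates

`generate_panel_scores()` produces the hierarchical structure the
battery assumes: per panel, a systematic utility shift (separately per
state), a procedure-level heterogeneity of that shift (`tau_shift`,
drawn once per procedure and applied to both states), Gaussian
between-expert noise on the VAS scale clipped to [0, 100], and a second
Delphi round that shrinks scores toward the round-1 panel median by
`round2_shrinkage` plus residual noise. Round-1 dispersion is
`expert_sd / (1 - s/2)` and the round-2 residual SD is derived so the
*final-round* marginal SD equals `expert_sd` — all downstream statistics
use final scores, so the preset parameterizes what they see.

The `study_emulation_preset()` fixes the reference conditions: 43
procedures of which 9 GBD-derived; an 18-expert original panel
(no shift, `expert_sd` 0.10, no heterogeneity) and a 15-expert
validation panel (shifts −0.14 pre / −0.08 post, `expert_sd` 0.16,
`tau_shift` 0.06); both panels shrink half-way. `tau_shift = 0.06` makes
the SD of paired panel differences about 0.075, consistent with
limits-of-agreement half-widths near 0.145.

Truth generation (`truth_ranges()`) reflects a portfolio of severe
semi-elective procedures: ages 50-80, preoperative utilities 0.40-0.70,
postoperative gains 0.05-0.20 capped at 0.85, perioperative mortality
0.5-3%. Two structural choices deserve explanation:

* **Severity coupling.** Long-term post-surgery survival is tied to the
  same disease that kills while waiting: the post-surgery excess hazard
  is a fraction 0.1-0.5 of the waiting mortality, saturating once
  waiting mortality exceeds 2% per month. Drawing the two independently
  produces procedures whose treated course is *deadlier* than waiting —
  and hence negative urgency — which contradicts the premise that these
  are indicated operations. The saturation encodes that successful
  surgery for even the most lethal untreated conditions (a
  rupture-prone aneurysm) leaves a far better prognosis than the
  untreated disease.
* **The urgency ladder.** True urgencies are laid out on an explicit
  ladder — linear from 0.02 to 0.06 DALY/month over the lower third of
  procedures, geometric up to 0.35 above it, jittered ±2% and randomly
  assigned — and each procedure's waiting mortality is calibrated by
  root-solving the cohort model so its true-QoL urgency sits on its
  rung. A triage portfolio is *selected* to span the urgency spectrum;
  iid parameter draws instead cluster urgencies, and in the dense
  regions the elicitation sampling noise (about 0.0025 DALY/month on
  the QoL-gap term; a few percent relative on the survival term)
  reorders many ranks — a property of the arbitrary clustering, not of
  the method. The ladder's linear-then-geometric shape keeps absolute
  spacing above the absolute noise at the bottom and relative spacing
  above the relative noise at the top.

Utility ranges deliberately stay away from the scale ends: with the
validation panel's round-1 dispersion (0.213 on the utility scale),
centres near 0 or 1 would clip enough Gaussian mass to bias panel means
by over 0.01, breaking the generator's contract that final-round means
are unbiased for truth plus shift. Within these ranges the measured
bias is below 0.006 per cell.

What the generator does **not** emulate: expert dropout between rounds,
free-text arguments and their influence, correlation of an expert's
scores across procedures (each score's noise is independent), non-
Gaussian (e.g. end-digit-preference) scoring, and any real procedure's
actual parameters. Parameter recovery on this synthetic preset therefore
demonstrates that the *statistical machinery* is correct and that the
*reference effect sizes are recoverable at these panel sizes* — not
that any particular hospital's estimates are right.

## Numerical choices and degenerate inputs

* Cohort occupancies are conserved by construction (the dead fraction is
  the complement), tested to 1e-12; death is absorbing.
* Waiting-mortality calibration uses `uniroot` on [1e-6, 0.6] with
  tolerance 1e-7; urgency is strictly increasing in waiting mortality,
  so the root is unique.
* Ties in ranking get average ranks for rho and id-order for display.
* A single-expert cell returns its mean with SE and CI flagged
  unavailable rather than erroring; an empty second panel makes pooling
  degrade to the first panel with a warning.
* All randomness flows from one root seed through deterministic
  per-module sub-seeds (`truths`, each panel, PSA), so stages are
  independently reproducible and identical configurations are
  byte-identical on disk.

## Problem sizes

The test suite and the acceptance script run the preset at its natural
size (43 procedures, 18 + 15 experts, two rounds) over ten seeds —
about half a minute end to end — with smaller cohorts (2-10 procedures,
4-12 experts) for unit-level properties and 100-seed calibration loops
where a rate is being verified. These sizes were chosen so that
Monte-Carlo error is comfortably below the tolerances being asserted.

## Limitations

The decision model scores an average patient per procedure: no
comorbidity adjustment, no disease progression to inoperability while
waiting (waiting harm is mortality plus lost utility only), no
individual-level heterogeneity. The mapping of the model's inputs to
seven parameters (age, two utilities, waiting mortality, perioperative
mortality, long-term survival, background life table) is this package's
reconstruction and is isolated behind `procedure_params()` so it can be
remapped. The validation battery quantifies agreement between two
panels; with more panels the mixed models generalize naturally
(study as a factor), but the Bland-Altman machinery is inherently
pairwise. Capacity allocation — turning the urgency ranking into an
operating-room schedule — is out of scope.
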