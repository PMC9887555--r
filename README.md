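# surgprio

Prioritizing semi-elective surgery by expected health loss per month of
delay.

When operating-room capacity is scarce — a pandemic wave, a staffing
crisis — hospitals must decide which non-acute procedures to schedule
first. `surgprio` implements a utilitarian triage strategy for that
decision: rank procedures by the expected *health loss per month of
surgical delay*, expressed in disability-adjusted life years (DALY) per
month, and quantify how robust that ranking is to the quality-of-life
(QoL) inputs on which it partly rests.

The package is aimed at health-economics and clinical-epidemiology teams
who need (a) a transparent cohort model of delay urgency, (b) tooling to
aggregate expert-panel QoL elicitations, and (c) a validation battery for
comparing QoL estimates across independent expert panels.

## The model

Each procedure is an average patient moving through a three-state,
monthly-cycle cohort model: **Preop** (waiting), **Postop** (operated),
**Dead**. While waiting, the monthly death probability combines
disease-related waiting mortality `p_wait` with background (life-table)
mortality; at the end of the delay the survivors undergo surgery and face
a one-time perioperative mortality `p_periop`; afterwards background and
post-surgery excess mortality (from the long-term survival fraction
`s_long` over a fixed horizon) combine additively on the hazard scale.
QALYs accrue each cycle as occupancy-weighted utility,
`(preop * q_pre + postop * q_post) / 12`. The urgency of a procedure is

```
DALY/month = [ QALY(delay = 0) - QALY(delay = d) ] / d        (d = 1 by default)
```

QoL weights `q_pre`, `q_post` come either from published disability
weights (`utility = 1 - disability weight`) or from expert panels scoring
health-state descriptions on a 0-100 visual analogue scale across two
Delphi rounds. The validation battery compares two panels' estimates
with:

* **Bland-Altman analysis** of paired per-procedure mean utilities
  (bias, 1.96-SD limits of agreement, observed extremes);
* a **random-intercept linear mixed model**
  `utility ~ study + state + (1 | procedure)` on individual expert
  scores (REML via `lme4`), whose study coefficient is the standardized
  mean difference between panels;
* the same model on per-cell **between-expert SDs** — the consensus
  measure (a lower SD is a higher degree of consensus);
* **Spearman rank correlation** between urgency rankings computed from
  one panel's QoL versus both panels pooled.

A synthetic-data module generates full two-panel, two-round score sets
with known truth — panel-level shifts, inflated dispersion,
procedure-level shift heterogeneity, round-2 shrinkage toward the
round-1 median — so every statistic in the battery can be checked by
parameter recovery.

## Worked example

```r
library(surgprio)

sim    <- simulate_study(1)      # 43 procedures, panels of 18 and 15 experts
report <- run_study(sim)
report
#> Two-panel validation study (43 procedures, 34 panel-rated)
#>   Bland-Altman bias: pre -0.140 [LoA -0.346, 0.065], post -0.053 [LoA -0.222, 0.115]
#>   study coefficient (scores): -0.097 [-0.108, -0.086]
#>   study coefficient (consensus SDs): 0.046 [0.038, 0.054]
#>   ranking robustness: Spearman rho = 0.993 (largest change: P27)

head(rank_procedures(report$urgency$original), 3)
#>  procedure_id daly_per_month rank
#>           P27      0.3134081    1
#>           P05      0.3100936    2
#>           P42      0.2998706    3
```

Reading the output: the simulated validation panel scores utilities
about 0.14 lower preoperatively and 0.05 lower postoperatively than the
original panel (Bland-Altman biases), individual scores average about
0.10 lower overall (score-model study coefficient), and the validation
panel's between-expert SDs run about 0.05 higher (less consensus). Yet
the urgency ranking computed from pooled QoL weights agrees with the
original-only ranking at Spearman rho = 0.993: the prioritization is
driven mainly by survival, so a systematic shift in QoL leaves the order
of procedures nearly unchanged. `P27` at rank 1 loses ~0.31 DALY per
month of delay — about 3.8 healthy life-years per year postponed.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/surgprio.R simulate --seed 7 --out out/
Rscript inst/cli/surgprio.R run-all  --seed 7 --in out/ --out out/
```

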