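# abxtimeout

Analytics for an automated **antibiotic time-out**: a stewardship
intervention in which physicians of inpatients reaching five days of
continuous therapy on targeted antimicrobials receive an automated alert
prompting them to stop the drug or document a rationale for continuing it.
The package is aimed at antimicrobial-stewardship and hospital-epidemiology
teams who want to run the alerting rule over medication-administration
records and evaluate the program the way such interventions are evaluated:
interrupted time series on monthly consumption, with a contemporaneous
non-targeted control group, plus annual infection-rate trend surveillance.

## What it computes

**Day-5 alert rule.** A patient-drug pair is alert-eligible on calendar day
*D* when each of the four preceding calendar days carries ≥ 2 dose
administrations of the drug, no gap between consecutive administrations in
that run exceeds 48 h, and an active order for the drug overlaps day *D*.
The scan emulates the daily batch and emits one auditable alert per
continuous course, routed to the attending and/or ID-consult physician
according to a configurable policy era.

**Consumption metrics.** Per drug and calendar month: mean duration of
therapy (antibiotic days of courses initiated that month divided by the
number of courses initiated — deliberately outlier-sensitive) and days of
therapy per 1000 patient-days (DOT/1000 PD, NHSN convention: one DOT per
patient per drug per dosed calendar day).

**Interrupted time series.** For each drug and metric, one segmented OLS
model on the monthly series y_t with change point t0:

    y_t = b0 + b1 (t - t0) + b2 I[t >= t0] + b3 (t - t0) I[t >= t0] + e_t

Centring time at t0 makes b0 the predicted value at the change point
without intervention, b2 the immediate (level) change, b1 the
pre-intervention slope and b3 the slope change; each is reported with a
t-based 95% CI on n − 4 residual df, and arbitrary linear combinations
w′β of the parameters are available with delta-method standard errors.

**HAI surveillance.** The multidrug-resistant *P. aeruginosa* rule
(resistant to meropenem or imipenem, or to ≥ 3 of the groups
ceftazidime/cefepime, piperacillin-tazobactam, ciprofloxacin/levofloxacin),
annual incidence rates per 1000 patient-days, and secular trends by Poisson
regression with a log patient-day offset,

    log E[count_t] = a + g·year_t + log(PD_t),   IRR = exp(g),

with Wald 95% CIs. CDI is rate-reported but excluded from trend testing by
default.

**Synthetic EHR generator.** Because institutional pharmacy data cannot be
shipped, a seeded generator emits dose events, order intervals, daily
census, admissions and annual infection counts whose monthly mean course
durations follow a configurable segmented-linear model — so the whole
pipeline is exercised end to end from one integer seed.

## Worked example

```r
library(abxtimeout)
bundle <- run_pipeline(demo_config(out_dir = "demo-out"))
cat(readLines(file.path("demo-out", "tables.txt")), sep = "\n")
```

The demonstration study spans monthly data 2007-01 to 2015-03 with change
point 2010-07: one targeted drug carrying an injected −1.0 day immediate
change in mean duration of therapy, one nontargeted null control. Under the
documented seed it prints:

```
Change in mean duration of therapy (days)
---------------------------------------------------------------------------------------------------------
drug        group        baseline  change  95% CI          p     slope  slope change  95% CI         p
cefepime    nontargeted  5.40      -0.08   -0.32 to  0.16  0.52  -0.01  0             -0.01 to 0.01  0.72
daptomycin  targeted     6.33      -1.04   -1.31 to -0.78  0.00  -0.01  0             -0.01 to 0.01  0.45
```

Read the targeted row as: the model predicts a baseline mean duration of
6.33 days at the change point; the time-out is associated with an immediate
drop of 1.04 days (95% CI −1.31 to −0.78, bracketing the injected −1.0),
with no long-term slope change. The control drug shows no effect (−0.08,
CI includes 0). The bundle also contains `alerts.csv` (3294 day-5 alerts
over 7729 courses under the demo seed), `monthly_consumption.csv`,
`hai_trends.csv` (e.g. VRE IRR 0.89/yr, 95% CI 0.87–0.91, against a
configured 0.90 trend) and a JSON run manifest.

A thin command-line front end wraps the same functions:

```sh
abx=$(Rscript -e 'cat(system.file("cli", "abx", package = "abxtimeout"))')
Rscript $abx demo --out demo-out
Rscript $abx its --input demo-out/monthly_consumption.csv --t0 2010-07 \
    --targeted daptomycin --nontargeted cefepime --out its.csv
```

(`simulate`, `scan`, `metrics`, `hai-trend` and `run` subcommands cover the
individual stages; see `inst/extdata/demo-scenario.yaml` for the scenario
schema.)

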