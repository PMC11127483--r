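---
title: "Methods: day-5 antibiotic time-out detection and stewardship evaluation"
author: "abxtimeout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-5 antibiotic time-out detection and stewardship evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxtimeout)
```

## The problem

Prolonged courses of broad-spectrum antimicrobials drive resistance,
*Clostridioides difficile* risk and cost, and much of the excess is simple
inertia: therapy continues past the point where it was re-justified. An
*antibiotic time-out* attacks this by prompting the treating physician, at a
fixed point in a course (here day 5), to either stop the drug or document a
rationale for continuing. This package implements the three analytic layers
such a program needs:

1. a **rule engine** that finds patient-drug pairs reaching day 5 of
   continuous therapy in medication-administration records;
2. **consumption metrics** aggregated monthly per drug; and
3. **evaluation models**: segmented (interrupted time series) regression on
   the consumption series with a contemporaneous control group of
   non-targeted drugs, and Poisson trend models for annual
   healthcare-associated-infection (HAI) rates.

A seeded synthetic EHR generator stands in for institutional data, which is
never shippable, so all properties of the pipeline are testable end to end.

## Time conventions

All instants are minute-resolution POSIXct in one implicit timezone (UTC);
calendar days split at midnight; months are calendar months. These
conventions are fixed because the alerting rule is phrased in days and
hours: a "day" in the eligibility rule is a calendar day, not a rolling
24-hour window, mirroring the daily-batch operation of such systems over
day-granular pharmacy data.

## The day-5 eligibility rule

A patient-drug is eligible for an alert on calendar day $D$ iff

* each of days $D-4, \dots, D-1$ contains $\ge 2$ administrations of the
  drug,
* every gap between consecutive administrations, from the first dose of day
  $D-4$ to the last dose of day $D-1$, is $\le 48$ h, and
* some active order for the drug overlaps day $D$ (interval overlap,
  start-inclusive, end-exclusive at day boundaries).

Decisions we fixed where the rule statement leaves latitude:

* **Gap scope.** The 48-hour constraint is applied to consecutive doses
  *within the qualifying 4-day run*, not the patient's entire history. Note
  that under the calendar-day reading with $\ge 2$ doses per day, two
  consecutive dosed days can never be more than 48 h apart, so the gap
  clause binds only under stricter thresholds (`gap_hours` is a parameter)
  — we keep it because it is part of the stated rule and guards alternative
  configurations.
* **Dose counting.** Administrations are counted as recorded; two doses a
  minute apart count as two, and no distinction is made for partial or held
  doses (every row of the dose table counts).
* **Deduplication.** An alert is emitted once per continuous course: after
  a first alert, a second one for the same patient-drug requires an
  intervening gap that breaks the rule (i.e. a new course). Repeated daily
  alerts would make alert counts meaningless as a workload measure.
* **Routing eras.** Recipient selection is a configuration
  (`routing_policy`), not hard-coded dates: attending-only; attending plus
  a duplicate to the ID-consult physician for consulted patients; or
  ID-physician-only for consulted patients. Consult status is an input flag
  per patient.

Correctness is established against a brute-force oracle that re-reads the
rule literally — counting doses day by day with explicit loops and deciding
order presence by enumerating all 1440 minutes of day $D$ — over randomized
instances and a systematic grid of half-day dose patterns, plus the
monotonicity property that adding a dose can never revoke eligibility.

## Courses and consumption metrics

The course is the unit of the duration metric but is not externally
defined, so we define it coherently with the alert rule: doses of a
patient-drug are partitioned greedily in time order, a new course starting
whenever the inter-dose gap exceeds 48 h (configurable). A course's
**antibiotic days** are its distinct dosed calendar days.

Per drug and month:

* `courses_initiated`: courses whose first dose falls in the month;
* `mean_duration` = antibiotic days of those courses / courses initiated.
  The full duration of a course is attributed to its initiation month,
  keeping numerator and denominator consistent and making the metric
  sensitive to outlying long courses — the mean is used (not the median)
  precisely for that sensitivity;
* `dot`: one day of therapy per patient per drug per dosed calendar day
  (the NHSN convention), attributed to the month in which the day actually
  falls; `dot_per_1000pd` = 1000 · DOT / patient-days from the daily
  census.

The duration numerator and DOT both use the distinct-dosed-day count; this
identification is an interpretation we document rather than an external
requirement. Conservation is exact by construction — summed monthly DOT
equals the number of distinct (patient, drug, day) dosed triples, and
summed initiations equal the course count — *when the reporting window
covers all dosed days*; a pipeline reporting only a study window leaves the
run-out of courses started in its final month uncounted, as a real monthly
report would.

## Segmented interrupted-time-series model

For a monthly series $y_t$ with first post-intervention month $t_0$, one
OLS model is fitted:

$$y_t = \beta_0 + \beta_1 (t - t_0) + \beta_2\, \mathbb{1}[t \ge t_0] +
\beta_3 (t - t_0)\, \mathbb{1}[t \ge t_0] + \varepsilon_t .$$

Centring at $t_0$ makes $\beta_0$ the predicted value at the change point
absent intervention, $\beta_2$ the immediate (level) change, $\beta_1$ the
baseline slope and $\beta_3$ the slope change; the first post month carries
the level change. Reported contrasts are linear combinations $w'\hat\beta$
with $SE = \sqrt{w' \hat V w}$.

Numerical and inferential choices:

* Plain OLS covariance by default — the estimator the method names — with a
  Newey–West HAC option (off by default) for autocorrelated residuals.
* $t$-distribution critical values on $n-4$ residual df (whether large-
  sample normal quantiles were ever intended is not decidable from the
  method's name; $t$ is the exact small-sample choice and converges to
  normal anyway).
* Missing months are dropped with a warning naming them, never imputed.
* Fitting requires $\ge 3$ observations per segment; a rank-deficient
  design raises a singularity error; per-drug failures in the batch report
  are flagged rows, not fatal errors.
* The change point is an explicit required parameter. In programs where an
  educational run-in precedes the alerting go-live, the period boundary
  (start of the campaign) is the natural default and is what the demo uses;
  any other month can be passed.

Exactness (any two-segment piecewise-linear series is interpolated with
zero residual at $10^{-9}$) and calibration (null $\beta_2$ p-values
uniform by Kolmogorov–Smirnov; 95% CI coverage of an injected $-1.0$ level
change within $[0.92, 0.98]$ at $\sigma = 0.3$ over a 42 + 57 month design)
are both asserted in the test suite.

## HAI classification and trends

The multidrug-resistant *P. aeruginosa* rule: resistant to meropenem **or**
imipenem, **or** to at least 3 of the 3 groups {ceftazidime/cefepime},
{piperacillin-tazobactam}, {ciprofloxacin/levofloxacin}. A group is
resistant when any member is; "unknown" never counts as resistant. The
defining sentence is grammatically ambiguous about whether the carbapenems
belong among the countable groups; we implement the literal "either … or"
reading in which carbapenem resistance alone suffices — with all three
non-carbapenem groups resistant the isolate qualifies regardless, so the
readings differ only on carbapenem-susceptible isolates, where the literal
reading is also the stricter count. The classifier is verified against a
literal re-encoding over the full $3^7$ truth table and is monotone in
resistance.

Annual trends: $\log E[\text{count}_t] = \alpha + \gamma\,\text{year}_t +
\log(\text{PD}_t)$ by Poisson ML; IRR $= e^\gamma$ with Wald 95% CI on the
log scale — the standard output of Poisson regression with an exposure
offset. Year enters as a linear integer covariate (calendar vs fiscal year
is labelling only; trend estimates are shift-invariant, and jointly scaling
counts and exposure leaves the IRR unchanged). CDI is excluded from formal
trend testing by default because its detection assay typically changes
within a surveillance period, confounding any secular trend; a flag forces
inclusion.

## The synthetic generator: what it emulates and what it does not

`generate_cohort()` draws, per drug and month, a Poisson number of course
initiations; each course's whole-day duration is Gaussian around the
segmented-linear monthly mean implied by the configuration (truncated below
at 1 day, rounded to whole days since the metrics are day-granular); doses
default to 2/day 12 h apart (08:00, 20:00) so dense courses satisfy the
alert rule by construction, with a sparse-dosing option (single-dose days,
skipped days) to exercise negative detector cases; each order interval
spans its course plus a 24 h tail, which is what makes "active order on the
fifth day" controllable; the census is a constant daily patient-day count
per month. Each course occupies its own opaque admission identifier — the
data model supports patients carrying several drugs and courses, but
keeping generated courses on distinct admissions makes course-level
bookkeeping in tests exact. `generate_hai_counts()` draws annual counts as
Poisson with mean $\text{rate}_0 \cdot RR^t \cdot \text{PD}_t / 1000$.

Default study conditions mirror a realistic large-hospital stewardship
evaluation: monthly series 2007-01–2015-03 (42 pre- and 57 post-change
months), change point 2010-07, ~40 courses per drug-month, baseline mean
durations ≈ 5–6 days with a −1.0 day injected immediate change on the
targeted drug and a null nontargeted control, per-course duration SD 2 days
(≈ 0.3 days SD on monthly means at 40 courses/month), 18 000 patient-days
per month, and nine years of HAI counts at 200 000 patient-days per year
with per-year rate ratios between 0.84 and 1.04. The demonstration seed is
20100701.

With duration noise 0 the monthly mean duration computed downstream equals
the configured segmented mean *exactly* when the configured means are
integers (durations are whole days); non-integer noiseless means are
rounded per course. Dosing times and inter-dose distributions are generator
conveniences, not claims about real pharmacy data. The generator does not
model ICU/ward structure, service lines, weekday effects, censoring at
discharge, correlated drug use within patients, or order modifications —
so passing tests demonstrate the *analytics* are correct and calibrated
under the stated generative model, not that real hospital data meet that
model's assumptions.

## Pipeline determinism and problem sizes

`run_pipeline()` chains simulate/load → alert scan → consumption → ITS →
HAI trends, writing RFC-4180 CSVs, rendered tables (rounded to 2 decimals)
and a JSON manifest with config echo, seed and row counts; identical
configuration and seed give a byte-identical bundle (the manifest contains
no wall-clock fields). Stage randomness derives from the single master
seed.

Test-suite simulation sizes were chosen to characterise the estimators
tightly while staying small: detector/oracle equivalence on 10 000
randomized instances plus a ~5 500-pattern systematic grid evaluated on two
days each; ITS calibration with 1000 null replicates (K-S uniformity) and
500 coverage replicates; Poisson CI coverage over 200 replicate
surveillance series; the full 2 187-row resistance truth table; and the
full-scale two-drug demonstration study run twice for bytewise
reproducibility.

## Known limitations

* OLS inference ignores autocorrelation unless the Newey–West option is
  enabled; monthly stewardship series can be autocorrelated.
* The alert scan is quadratic in the worst case over a patient-drug's
  dosed days; it is sized for cohort analytics, not streaming operation.
* Mean length of stay is a simple discharge-month mean, provided as a
  balance check, not a risk-adjusted utilisation model.
* ESBL/CRE/VRE/MRSA category labels are taken as input; only the MDR
  *P. aeruginosa* rule is computed from susceptibility profiles.
* No email transport, scheduling daemon, or EHR connectivity: the package
  is the analytic engine, with CSV contracts at every stage boundary.
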