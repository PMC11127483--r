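# Example simulation scenario for the `abx` command line tool.
# One targeted drug with an injected -1.0 day immediate change in mean
# duration of therapy at the intervention month, and one nontargeted
# null-control drug.
study_start: "2007-01"
study_end: "2015-03"
intervention_month: "2010-07"
duration_noise: 2
census_mean_monthly: 18000
seed: 20100701
drugs:
  - drug: daptomycin
    group: targeted
    baseline_duration: 6.2
    pre_slope: -0.01
    level_change: -1.0
    slope_change: 0.0
    courses_per_month: 40
  - drug: cefepime
    group: nontargeted
    baseline_duration: 5.3
    pre_slope: -0.01
    level_change: 0.0
    slope_change: 0.0
    courses_per_month: 40
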