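# adlwatch

Unobtrusive activity monitoring for elderly occupants from smart-meter
data.

Difficulties with instrumental activities of daily living — cooking,
laundry, ironing — are early indicators of declining well-being, and many
of those activities run through hand-operated electrical appliances whose
usage is visible in a household's power trace.  `adlwatch` is for
researchers and developers of active-and-assisted-living (AAL) services
who want to infer the *regularity* of such activities from metering data
alone: no cameras, no wearables, no extra sensors.  It covers the whole
pipeline — synthetic data with controlled anomalies, appliance state and
activation extraction, a classical disaggregation baseline, day scoring,
anomaly classification, and external-agent feedback — so every stage can
be evaluated without access to annotated field data.

## The method

For each day, the time spent on an activity (the summed durations of its
appliances' activations) is binned over the 24 hours and normalised into
an **activity curve** `P`.  After a passive 51-day observation phase has
filled a store of curves `P_1 … P_n`, a monitored day is scored with the
generalised Jensen–Shannon divergence

    JSD_π(P_1…P_n) = Σ_i π_i D(P_i ‖ M),   M = Σ_i π_i P_i,
    D(P ‖ M)       = Σ_x P(x) log( P(x) / M(x) ),

where the weights `π_i` favour days according to external-agent feedback:
`π_i = 1/(N1 + β·N2)` for a feedback day and `β/(N1 + β·N2)` otherwise
(`β ≥ 2`, `Σ π_i = 1`).  The day score is `JSD` between the day's curve
and the π-weighted mixture of the stored curves (bounded by `log 2`).  A
day is flagged anomalous when its score leaves the interval
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` computed over leave-one-out scores of the
stored days, and the anomaly is classified as **absence** (no usage),
**night usage** (an activation starting in 0–4 h) or **abnormal usage
time**.  Feedback folds misidentified anomalies back into the store;
normal days rotate in through a forgetting policy that replaces the
oldest unlabelled entry.

## Worked example

```r
library(adlwatch)

# a year-scale synthetic household with a diurnal kettle routine
ds <- generate_household(house4_profile(), n_days = 351, seed = 42)
ds <- inject_anomalies(ds, "night_usage",     0.10, seed = 43, days = 52:351)
ds <- inject_anomalies(ds, "divergent_usage", 0.10, seed = 44, days = 52:351)
ds
#> <labelled_dataset> 351 days from 2014-09-01, 1 appliance(s) @ 8s
#>   day labels: divergent_usage=30, night_usage=30, normal=291

cfg <- pipeline_config(observation_days = 51)
run <- monitor_household(ds$appliances, cfg)
table(run$reports$decision)
#> anomalous    normal
#>        32       268

labels <- ds$labels[ds$labels$date %in% run$reports$date, ]
classification_metrics(day_level_confusion(run$reports, labels))
#> precision 0.875, recall 0.467, f1 0.609
per_class_recall(run$reports, ds$labels)
#> divergent_usage     night_usage
#>      0.90000000      0.03333333
```

Reading these numbers: of the 300 monitored days, 32 were flagged; days
whose whole routine was shifted by 4–8 h (`divergent_usage`) are caught
almost always (recall 0.90), and false alarms are few (precision 0.875).
Days that merely *add* one or two night-time boils to an otherwise normal
routine are hard for the divergence score to separate from day-to-day
sampling noise — the methods vignette
(`vignettes/activity-monitoring.Rmd`) derives why, and why the effect is
intrinsic to the curve-plus-IQR design rather than a bug.  With the
night-habit preset (`house11_profile()`) injected night days are by
construction part of the observed routine and go undetected: what counts
as anomalous is relative to the occupant.

`write_report(run$reports, "report.jsonl")` serialises one JSON record
per day (score, decision interval, class, contributing activations) for
the external agent; `read_report()` round-trips it.

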