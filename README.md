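# drprogress

Interval-censored survival modelling of diabetic retinopathy (DR)
progression, and the personalized screening intervals it enables.

## The problem

Eyes of people with diabetes are screened on a fixed annual calendar, yet
the risk of DR progression varies enormously between individuals. With
longitudinal exam data — an ICDRDSS grade (0–4) and a DME flag per eye per
year, plus twelve baseline covariates — the time to progression (first
deterioration of the DR grade or new onset of DME) can be modelled and
used to stretch screening intervals for slow progressors while keeping
delayed detection rare. The package is aimed at biostatisticians and
screening-programme modellers working with such visit tables.

## The model

Each eye's progression time is observed only up to an interval: it lies
between the last progression-free exam at time *t* and the detecting exam
at time *t′*, or beyond the last exam (right censoring), giving records
⟨x, t, t′, e⟩. The survival distribution given covariates x is a
fixed-size mixture of K Weibull atoms,

    S(t | x) = Σᵢ φ_{i|x} · exp(−(t/αᵢ)^βᵢ),

with atom parameters drawn once from log-normal priors and frozen; a
three-layer perceptron maps x to the simplex weights φ via a softmax.
Training minimizes the interval-censored negative log-likelihood

    L = −Σᵢ ln Σⱼ φ_{j|xᵢ} exp(−(tᵢ/αⱼ)^βⱼ)
        − γ Σᵢ eᵢ ln Σⱼ φ_{j|xᵢ} (1 − exp(−(t′ᵢ/αⱼ)^βⱼ))

by mini-batch SGD. The predicted time to progression is the mode of the
fitted density and doubles as the risk score (smaller time = higher
risk). Evaluation follows the survival-analysis standards: Harrell's
C-index, IPCW Brier / integrated Brier score, time-dependent ROC,
Kaplan–Meier with one-sided log-rank, participant-clustered bootstrap
CIs. A policy layer converts predicted times into recommended screening
years, `min(5, ⌊T̂⌋ + 1)`, and accounts for screening-frequency reduction,
delayed detection, eye-year incidence and adjusted relative rate
reductions. A seeded simulator generates realistic synthetic cohorts with
known ground truth for all of the above.

See `vignettes/weibull-mixture-progression.Rmd` for the full methods
account.

## Worked example

```r
library(drprogress)

# a synthetic cohort: 1,000 participants, two eyes each, annual exams
sim <- simulate_cohort(sim_scenario(n_participants = 1000, seed = 42))

# interval-censored records for the "any progression" endpoint
baseline <- sim$visits[!duplicated(paste(sim$visits$participant_id,
                                         sim$visits$eye)), ]
encoder <- fit_feature_encoder(baseline)
records <- derive_records(sim$visits, "any", encoder)
nrow(records); sum(records$event)
#> [1] 2000
#> [1] 143

# fit the mixture-of-Weibull model on the baseline covariates
model <- fit_progression_model(records, atom_prior(), train_config(seed = 1))

# predicted time to progression = risk score (smaller = higher risk)
pred <- predict_time_batch(model, record_features(records))
round(concordance_index(pred, records), 3)
#> [1] 0.892

# personalized screening plan versus annual screening
plan <- screening_plan(records, pred)
m <- plan_metrics(plan)
round(c(interval = m$mean_interval_months, reduction = m$reduction_pct,
        delayed_any = m$delayed_any_pct), 2)
#>    interval   reduction delayed_any
#>       59.16       79.72        3.90
```

2,000 eyes yield 143 progression events within the 5-year horizon (~7%).
The in-sample concordance of 0.892 says the model orders progressing eyes
almost as well as the data allow; the plan stretches the mean screening
interval from 12 to 59 months (a 79.7% cut in exams) at the cost of
detecting 3.9% of eyes' progressions later than annual screening would
have. Held-out numbers are lower (see the acceptance script).

A command-line wrapper over the same pipeline lives at
`inst/cli/drprogress.R` (verbs `simulate`, `derive`, `fit`, `predict`,
`evaluate`, `screen-plan`).

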