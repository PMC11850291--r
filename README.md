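# rtlsfall

Movement-based in-hospital fall-risk modelling from real-time location
system (RTLS) event streams and admission clinical records.

Hospital falls are frequent, harmful and poorly anticipated by one-off
admission risk scores, because the strongest short-term signal — a
patient's declining physical activity and gait speed — evolves during the
stay. RTLS wristbands log a `(timestamp, latitude, longitude)` record every
time a patient's position changes, turning routine care into a continuous
movement record. `rtlsfall` is for biostatisticians and clinical data
scientists who want to build and evaluate fall-risk models on such data:
it engineers the movement feature set, assembles the clinical covariates,
trains three gradient-boosted classifiers (clinical-only, RTLS-only,
combined) and runs a full comparative evaluation. A synthetic cohort
generator with configurable, known effect sizes makes every stage testable
without access to protected hospital data.

## The feature model

Consecutive location events of one patient define movement segments. For
events *k* and *k+1*:

    distance_k = haversine(lat_k, lng_k, lat_{k+1}, lng_{k+1})   (r = 6371 km, meters)
    Δtime_k    = T_{k+1} − T_k                                   (seconds)
    velocity_k = distance_k / Δtime_k                            (m/s)

Because the system records only location changes, Δtime includes the dwell
before the move, so velocity is dwell-diluted. Per patient-day, segments
(assigned to the calendar day of their earlier, "index" timestamp)
aggregate to seven metrics:

    total distance   Σ distance_k                 daily speed   Σ distance_k / Σ Δtime_k
    max velocity     max velocity_k               velocity σ    population SD of velocity_k
    top-20% active   100 · Σ{v ≥ 1.18} Δtime_k / Σ Δtime_k
    top-50% active   100 · Σ{v ≥ 0.26} Δtime_k / Σ Δtime_k
    not moving       100 · Σ{v ≤ 0.02} Δtime_k / Σ Δtime_k

with velocity thresholds of 1.18 / 0.26 / 0.02 m/s (top-20%, median and
lower-20% reference velocities; 1.18 m/s is normal adult walking speed).
Each metric contributes its first-day, last-day, mean and median value over
the stay: 28 movement features per patient. Faller streams are censored at
the fall first, so "last day" is the last day of pre-fall movement. The 27
clinical variables (demographics, admission vitals, drug exposures, 16
labs) pass a 70% availability filter, first-measurement selection and
5-nearest-neighbour imputation.

Models are XGBoost classifiers tuned by stratified 10-fold CV grid search
on a stratified 8:2 split, with the operating cutoff maximising the Youden
index on out-of-fold predictions. Evaluation: 1000-iteration paired
bootstrap (AUROC / AUPRC / Brier and threshold metrics) with
Kruskal–Wallis + Dunn comparison across models, decision-curve net benefit
`TP/n − (FP/n)·p_t/(1−p_t)`, DeLong tests and subgroup AUROCs.

## Worked example

```r
library(rtlsfall)

cfg    <- simulation_config(n_patients = 300, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <fall_cohort> 300 patients (63 fallers), 135002 RTLS events

rt <- rtls_features(cohort)       # censor, exclude, segment, aggregate
cl <- clinical_features(cohort)   # filter, impute, encode

ids      <- rt$labels$patient_id
combined <- cbind(cl$features[match(ids, cl$features$patient_id), ],
                  rt$features[match(ids, rt$features$patient_id), rtls_feature_names()])
y  <- rt$labels$fall
sp <- split_cohort(combined, y, ratio = 0.8, seed = 42)

bundle <- train_model(combined[sp$train, ], y[sp$train], feature_set = "combined",
                      grid = small_grid(), folds = 10, seed = 42)
bundle
#> <fall_model:combined> 58 features; cutoff 0.102 (J = 0.582); CV AUROC 0.852

pr   <- predict_risk(bundle, combined[sp$test, ])
boot <- bootstrap_compare(list(combined = pr$prob), y[sp$test],
                          cutoffs = c(combined = bundle$cutoff),
                          n_boot = 1000, seed = 42)
boot
#> <fall_bootstrap> 1000 iterations
#>     model metric               point
#>  combined  auroc 0.918 (0.828-0.984)
#>  combined  auprc 0.768 (0.541-0.956)
#>  combined  brier 0.091 (0.040-0.154)

feature_importance(bundle, combined[sp$test, ], top_n = 5)
#>                 feature mean_abs_attribution rank
#> 1  max_velocity_ms_last            0.9305744    1
#> 2 not_moving_ratio_last            0.8962622    2
#> 3              sedative            0.5819318    3
#> 4     top20_active_mean            0.5359151    4
#> 5                   dbp            0.4579131    5
```

Reading the output: the combined model separates fallers from non-fallers
with a test AUROC of 0.918 (95% bootstrap CI 0.828–0.984) on this
300-patient synthetic cohort; the Youden-optimal cutoff calls a patient
high-risk above probability 0.102. The top-ranked attributions are
last-day movement features (maximum velocity, not-moving ratio) alongside
sedative exposure — the pattern the generator plants: mobility decline just
before the fall, plus clinical vulnerability markers.

`run_pipeline()` wires all stages together and writes feature tables,
metrics, decision curves, subgroup results and a reproducibility manifest
to a run directory; `inst/cli/rtlsfall` is a thin command-line wrapper
(`simulate`, `features`, `run`) over the same functions.

## Scope

The movement model, thresholds and cohort contrasts are documented in
`vignettes/fall-risk-modelling.Rmd`, including what the synthetic
generator does and does not emulate. Ward floor-plan realism, sensor
noise, recurrent falls and real department-code mappings are out of scope.
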