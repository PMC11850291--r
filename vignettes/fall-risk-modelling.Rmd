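---
title: "Movement-based in-hospital fall-risk modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based in-hospital fall-risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inpatient falls are among the most frequent adverse events in hospitals.
Conventional fall-risk scores are taken at admission and cannot follow the
day-to-day evolution of a patient's mobility, even though declining physical
activity and gait speed immediately precede many falls. Real-time location
systems (RTLS) embedded in patient wristbands log a position record every
time the wearer's location changes, which makes a patient's movement
history available as a by-product of routine care.

`rtlsfall` implements a complete modelling pipeline on top of such data:

1. engineer per-patient movement features from raw location-change events;
2. assemble a standard clinical covariate set from admission EMR data;
3. train three gradient-boosted classifiers — clinical-only, movement-only
   (RTLS) and combined — for the first in-hospital fall;
4. evaluate and compare them with a paired bootstrap, decision-curve
   analysis, DeLong tests and subgroup statistics.

Because real inpatient RTLS streams are protected data, the package ships a
synthetic cohort generator whose defaults encode the study conditions the
pipeline is designed for. Every stage is exercised and tested against the
generator; nothing in the package requires access to hospital data.

## Movement feature engineering

### Segment physics

Events for one patient form an ordered stream of `(timestamp, lat, lng)`
records. Each consecutive pair becomes a *movement segment* carrying

- distance: the great-circle (haversine) distance between the two
  coordinates on a sphere of radius 6371 km, in meters;
- `dtime`: the elapsed time in seconds;
- velocity: distance / `dtime`, in m/s.

A segment is indexed by the *earlier* timestamp of its pair; that reference
point also decides which calendar day (UTC) the segment belongs to,
including segments that span midnight. Segments with `dtime = 0` (duplicate
clock readings from a second-resolution logger) have undefined velocity and
are dropped with a counter rather than patched — the least-assumption
choice.

Because the logger only writes on location change, a segment's elapsed time
includes the dwell at the origin location, so segment velocity is a
*dwell-diluted* speed: a 60 m walk after a 10-minute rest yields a low
velocity even at a brisk gait. This is a property of event-triggered
logging, not a defect; the activity ratios below are built on exactly this
dilution.

### Daily metrics and activity ratios

Per patient-day the package computes seven metrics: total distance (m),
daily speed (total distance / total elapsed time — algebraically the
time-weighted mean of segment velocities), maximum segment velocity,
population standard deviation of segment velocities (a single-segment day
yields 0), and three activity ratios: the percentage of tracked time spent
in segments at or above the top-20% velocity threshold, at or above the
median threshold, and at or below the lower-20% threshold ("not moving").

The operating thresholds default to fixed reference values of 1.18, 0.26
and 0.02 m/s — the top-20%, median and lower-20% velocities of a reference
inpatient population, with 1.18 m/s corresponding to normal adult walking
speed. Fixed thresholds are the recommended mode so that features mean the
same thing across cohorts; `derive_thresholds()` recomputes them from a
pooled velocity distribution (linear-interpolation percentiles) when a
cohort-specific calibration is wanted.

### Temporal aggregation and censoring

For each of the seven metrics the pipeline takes the value on the first and
last day with recorded movement plus the mean and median over all recorded
days, giving 28 features per patient. Days without any segment are skipped,
not zero-filled: an unrecorded day is missing data, and zero-filling would
fabricate immobility.

For fallers, events are censored at the fall before feature engineering
(the observation window is admission to the fall), so "last day" means the
last day with pre-fall movement. Two censoring modes exist: `strict` keeps
only events strictly before the fall timestamp (default) and `fall_day`
keeps the whole fall day — covering both readings of an
admission-to-fall-day window. Patients with fewer than 2 usable events
(overall, or pre-fall for fallers) cannot contribute a single segment and
are excluded, with a per-rule count log mirroring a cohort-refinement
flowchart.

## Clinical features

The clinical table carries 27 variables: sex, age, length of stay (for
fallers: admission to fall day), department category (medicine / major
surgery / minor surgery / others), ICU admission, SBP, DBP, pulse rate,
BMI, sedative and peridol exposure (binary), and 16 laboratory values
(albumin, ALP, ALT, AST, total bilirubin, BUN, calcium, total cholesterol,
creatinine, glucose, haematocrit, haemoglobin, phosphate, total protein,
RDW, uric acid). Drug exposures are encoded binary — the baseline-table
presentation of such cohorts — though a numeric dose column passes through
unchanged if provided.

Preprocessing applies a 70% availability filter (variables observed in at
least 70% of patients are kept), earliest-timestamp selection for repeated
measurements (ties broken by input order), and k-nearest-neighbour
imputation: each missing numeric cell is replaced by the mean of that
column over the k = 5 nearest rows, with distances computed as the root
mean squared difference over mutually observed z-scored numeric features,
and neighbours restricted to rows where the target is observed.
Categorical cells take the mode of the same neighbours; a row missing every
numeric value falls back to column means with a warning. The choice k = 5
is a common default; the imputation is deterministic and idempotent, and
imputed values always lie within the observed range of their column. The
design encoding one-hot-expands the department (27 variables become a
30-column numeric design).

## Models and evaluation

Three XGBoost classifiers (clinical, RTLS, combined) are trained on a
stratified 8:2 split. Stratification — of both the split and the
cross-validation folds — is a deliberate strengthening of a plain random
split: at a ~21% event rate and a few hundred patients, unstratified
10-fold splits can produce single-class folds. Hyperparameters are chosen
by grid search maximising mean out-of-fold AUROC over stratified 10-fold
cross-validation; the default grid spans `max_depth` {2, 3, 4}, `eta`
{0.05, 0.1}, `nrounds` {100, 300} and `min_child_weight` {1, 5}. The
operating cutoff maximises the Youden index (J = sensitivity +
specificity − 1, ties resolved to the lowest threshold) on the winning
configuration's out-of-fold predictions — never on test data, which closes
a leakage path. Both the J statistic and the probability cutoff are
reported, since "Youden index" is used for either in the literature.

Evaluation on the held-out test set uses 1000 bootstrap iterations with
identical resample indices across models, so every comparison is paired;
single-class resamples are rejected and redrawn to keep the iteration count
fixed. AUROC is the concordance probability with half credit for ties
(verified against exhaustive pair counting), AUPRC the non-interpolated
step area, Brier the mean squared probability error. Confidence intervals
are percentile 2.5/97.5. The three models' per-metric bootstrap
distributions are compared with a Kruskal–Wallis test followed by Dunn's
pairwise z-tests (rank sums with tie correction, Bonferroni ×3). Treating
bootstrap replicates as independent observations overstates evidence —
the replicates share the one test set — so those p-values should be read
as descriptive flags, not as inference about new patients.

Decision-curve analysis reports net benefit NB(p~t~) = TP/n −
(FP/n)·p~t~/(1−p~t~) over thresholds 0.01–0.99 with treat-all/treat-none
references. When the package summarises "dominance" of one model over a
threshold band (e.g. 0.1–0.5), it compares band-mean net benefit:
pointwise comparison at every grid step is dominated by the noise of a few
reclassified patients. DeLong's placement-value test compares correlated
AUROCs of two models on the same patients; subgroup contrasts (age
dichotomised at 65 — a 65-year-old is in the lower stratum — sex, LOS at 7
days) use the same variance estimator for independent strata. Feature
importances are mean absolute TreeSHAP attributions from the boosting
library, whose per-prediction sums (plus base value) equal the model
margin.

## The synthetic cohort generator

### Movement model

Patients hop between named waypoints on a ward (~200 m × 200 m bounding box
at latitude 37.28°, a 4 × 4 waypoint grid by default): dwell at a waypoint,
then walk straight to a *different* waypoint at the patient's gait speed,
emitting an event only on arrival — exactly the logging discipline the
feature engine expects. Waypoint chains are generated so consecutive
positions always differ, and a day's trips stop when the day is exhausted.
Dwells are a two-component exponential mixture (short "active-period"
dwells, mean 60 s with probability 0.6; long rests, mean 2000 s), which
spreads segment velocities across all three activity thresholds.

Defaults are tuned to realistic orders of magnitude for an inpatient
population: ~60 trips/day at a 1.3 m/s gait gives a median daily total
distance around 4.6 km. One structural constraint deserves note: because
chained events tile time completely (every second of a stay belongs to some
segment), daily speed is approximately daily distance / 86400 s on interior
days — about 0.05 m/s here. Observed hospital tables reporting ~4.6 km
alongside ~0.07 m/s imply recording gaps that break this tiling; the
generator reproduces the distance scale and accepts the slightly lower
speed scale rather than simulating logger dropouts.

Between-patient heterogeneity comes from per-patient gait speed
(N(1.3, 0.15) m/s) and a log-normal activity multiplier (sdlog 0.45, the
spread implied by a 2.8–6.5 km IQR); day-to-day condition fluctuation from
log-normal day multipliers on pace (sdlog 0.25; dwells scale reciprocally
so the whole day slows) and on trip count (sdlog 0.35). Without day-level
fluctuation, a within-patient decline would be near-noiselessly detectable
and every model would saturate.

### Fall effects

Fallers decline over the final 3 days before the fall (linear ramp to full
effect on the fall day): gait speed × 0.65 with reciprocally longer dwells
(so the whole day slows, not just the walking legs), trip count × 0.75,
and a fall-day trip inflation × 1.25 emulating restless extra movement.
The per-day speed factor of 0.65 is chosen so the *stay-averaged* speed
contrast between groups lands near the 0.75 ratio reported for real faller
cohorts (0.06 vs 0.08 m/s) — the decline only acts on the last few days,
so the per-day factor must be deeper than the stay-wide ratio.

The fall timestamp is placed one second after the faller's last recorded
movement of the fall day, and one post-fall day of events is still
generated: censoring is the feature engine's job, and this placement makes
strict censoring remove whole days rather than truncating the fall day
mid-way. That matters for the null-signal control: with mid-day falls, a
truncated last day would make faller last-day totals systematically
smaller even with every effect switched off, and the "no-signal" cohort
would not be signal-free.

### Clinical covariates

The EMR table reproduces the group contrasts reported for real faller
cohorts: male fraction +16 pp, age +3.5 y, LOS × 1.5, sedative use 43% vs
17%, peridol 13% vs 6%, ICU 11% vs 5%, department shifted toward medicine,
pulse +4.2/min, BMI −0.8, RDW +0.9%, plus the smaller laboratory shifts,
each in its native unit. Right-skewed labs (ALP, ALT, AST, bilirubin, BUN,
creatinine, glucose) are log-normal with matched mean and SD.

Covariates are *not* drawn independently: a latent standard-normal frailty
factor (weight 0.5) enters exposures on the logit scale and shifted labs
along the direction of their group contrast, so sicker patients jointly
show higher RDW, pulse and sedative use and longer stays. Independent
draws would make the multivariate clinical signal far stronger than any
single marginal contrast suggests — combining many independent weak
markers is easy — and the clinical-only model would be unrealistically
good. The frailty weight is calibrated so the clinical-only model performs
in the range reported for admission-data models of this kind (AUROC ≈
0.65–0.75). Frailty deliberately does not touch movement: the two data
sources contribute near-independently, which is also what interaction
analyses on real data report. Missing-at-random gaps (default 5%) are
injected into vital/lab cells only.

### What the generator does not emulate

Sensor noise and position jitter, multi-floor geometry, room semantics,
logger dropouts, recurrent falls, informative (non-random) lab
missingness, and correlations between clinical state and movement. Passing
tests on this generator therefore demonstrate that the pipeline's
machinery is correct and that it recovers planted effects of realistic
size — not that the models would reach any particular performance on real
hospital data.

## Numerical and operating choices

- Units are meters and seconds throughout; ratios on the 0–100% scale.
- Timestamps are continuous (fractional seconds) POSIXct in UTC; text IO
  uses microsecond ISO-8601. Continuous clocks let the
  generator-vs-feature-engine consistency checks hold to 1e-9.
- Velocity SD uses the population convention (divide by n).
- Percentiles use linear interpolation between order statistics.
- Degenerate threshold pools (percentiles not strictly ordered) warn
  rather than fail.
- Coordinates stay in decimal degrees; the haversine handles curvature, no
  projection step. Within a ward-sized box, shifting all longitudes by a
  constant changes no feature beyond 1e-6 relative.
- Simulation studies in the test-suite and the acceptance script run the
  models at a single documented hyperparameter point (`small_grid()`:
  depth 3, eta 0.1, 150 rounds) with stratified 10-fold CV and n = 600
  patients per cohort (10–20 seeds per study). The full default grid is
  the recommended setting for a single analysis; repeated-seed studies use
  the fixed point because grid refits change no qualitative conclusion.
- All boosting runs single-threaded, making every pipeline stage
  bit-reproducible from the manifest.

## Known limitations

The bootstrap comparison inherits the single-test-set caveat above; the
Youden cutoff is chosen on out-of-fold training predictions and can be
conservative for small folds; the KNN imputer is O(n²) in patients and
intended for cohort-scale (hundreds to thousands), not registry-scale,
tables; and with ~25 events in a 120-patient test set, single-split AUROC
differences of ±0.03 between models are within split noise — which is why
the package's own checks aggregate over repeated simulated studies instead
of trusting one split.
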