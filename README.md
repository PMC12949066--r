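# dyadsync

Interpersonal cardiac synchrony and heart rate variability analysis for
small-group studies.

## What this package is for

Studies of *physiological synchrony* record beat-to-beat (R-R) heart
intervals from every member of a small interacting group — say, 4–6
classmates listening to a story and then discussing it — and ask whether
pairs of people whose heart-rate fluctuations align are also the pairs who
are friends, feel close, or share an emotional experience. `dyadsync`
implements that analysis chain end to end, for researchers in
psychophysiology and developmental/social neuroscience:

- **Preprocessing** (`read_rr_export`, `correct_outliers`,
  `interpolate_gaps`, `preprocess_rr`, `resample_heart_rate`): the 30 %
  outlier rule against the last retained beat, linear gap filling above
  2 s, exclusion at ≥ 10 % changed data, and monotone-cubic 1 Hz
  heart-rate resampling.
- **HF HRV** (`hf_hrv_windows`): high-frequency (0.15–0.4 Hz) spectral
  power of the tachogram in 120-s windows shifted by 60 s — the standard
  index of parasympathetic (vagal) activity.
- **Cross-wavelet synchrony** (`cwt_morlet`, `cross_power`,
  `band_interval_max`, `truncate_and_zscore`): Morlet ($\omega_0 = 6$)
  cross-wavelet power of two heart-rate trajectories
  $|W_a W_b^*|$, reduced to per-20-s maxima in the HF (0.125–0.5 Hz) and
  LF (0.031–0.125 Hz) bands, truncated to 8 min (story) / 10 min
  (discussion) and z-scored against the pooled sample.
- **Dyadic measures** (`affect_coherence`, `empathic_accuracy`,
  `friendship_status`, `closeness_sum`, `liking_sum`, `cronbach_alpha`,
  `build_dyad_table`): affect-grid similarity
  $\sqrt{8} - \lVert(v_a,r_a)-(v_b,r_b)\rVert_2$, nomination-based
  friendship, IOS closeness and 8-item liking aggregates.
- **Multilevel models** (`icc_components`, `screen_covariates`,
  `select_structure`, `fit_model`, `marginal_r2`): nlme-backed mixed
  models with group/dyad (or group/subject) random intercepts, optional
  random slopes for time, and AR(1) residuals within unit-phase.
- **Synthetic cohort** (`cohort_config`, `generate_cohort`,
  `score_recovery`): a fully seeded generator of rosters, questionnaires
  and *coupled* cardiac beat series (integrate-and-fire over a rate
  process with shared band-limited drives), with planted effects so the
  whole chain can be validated without participant data.
- **Pipeline** (`run_pipeline`, `inst/scripts/dyadsync-cli.R`): one JSON
  config, CSV/JSON artifacts per stage, deterministic reruns.

See `vignettes/methods.Rmd` for the models, assumptions, numerical
choices, and what the synthetic validation does and does not establish.

## Worked example

Generate a small synthetic cohort, run the chain, and fit the dyadic
LF-synchrony model:

```r
library(dyadsync)

cfg    <- cohort_config(n_groups = 3, seed = 42)
cohort <- generate_cohort(cfg)

prep  <- preprocess_cohort(cohort$rr)
sync  <- compute_synchrony_table(prep$series, cohort$roster$dyads)
dyads <- build_dyad_table(cohort$roster, cohort$questionnaires)

fit <- fit_model(synchrony_model_spec("lf_z"),
                 build_synchrony_model_table(sync, dyads))
fit
```

```
<mm_fit> lf_z on 972 obs / 18 dyad_id units; marginal R2 = 0.117
  AR(1) phi = 0.496
                        term estimate  lower upper p_value
1                (Intercept)   -1.205 -3.062 0.652  0.2031
2            phasediscussion    0.056 -0.147 0.259  0.5906
3                       time   -0.002 -0.014 0.009  0.6920
4  gender_combofemale_female    0.249 -0.408 0.906  0.3892
5      gender_combomale_male    0.004 -0.356 0.365  0.9788
6           friendshipmutual    0.908  0.252 1.565  0.0148
7              closeness_sum   -0.069 -0.224 0.086  0.3185
8                 liking_sum    0.011 -0.277 0.299  0.9306
9           affect_coherence   -0.017 -0.302 0.268  0.8888
10               arousal_sum    0.158 -0.082 0.397  0.1579
11               valence_sum    0.042 -0.223 0.306  0.7139
12         empathic_accuracy    0.091 -0.156 0.339  0.4009
```

Reading the output: synchrony is in pooled z-units, so the
`friendshipmutual` estimate of 0.91 says mutual-friend dyads run about
0.9 SD above non-friend dyads in LF synchrony in this (tiny, strongly
coupled-by-construction) cohort, with a 95 % interval excluding zero; the
AR(1) parameter 0.50 is the lag-one correlation of neighbouring 20-s
residuals within a dyad-phase; the marginal R² of 0.117 is the share of
variance carried by the fixed effects. At the realistic 30-group scale
the planted mutual-friendship effect is ~0.24 z and the planted negative
valence effect on HF synchrony ~−0.1 z; the acceptance suite verifies
both signs are recovered in ≥ 80 % of replicates.

The same run via the pipeline driver:

```r
run_pipeline(list(out_dir = "run1", seed = 42,
                  synthetic = list(n_groups = 3)))
```

writes `preprocess_reports.csv`, `hrv_windows.csv`, `synchrony.csv`,
`dyads.csv`, `subjects.csv`, per-model coefficient tables,
`model_meta.json`, `recovery.csv` and a manifest into `run1/`. The CLI
equivalent is
`Rscript inst/scripts/dyadsync-cli.R all --config run.json`
(see `inst/extdata/example_config.json`).

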