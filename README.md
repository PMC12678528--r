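# wmlr — wave-masked linear reconstruction of 12-lead ECGs

Clinical 12-lead ECGs are often unavailable where monitoring is cheap:
wearables and reduced-lead recorders capture only a few leads. Because the
heart's electrical activity projects approximately linearly onto the body
surface, the missing precordial leads V1–V6 can be estimated from an
available subset, and the four limb leads III, aVR, aVL, aVF follow
algebraically from leads I and II. `wmlr` implements such a reconstruction
for the reduced lead set {I, II, V3}, with one twist: before fitting, the
P wave, QRS complex and T wave are *isolated* into extra input channels by
zero-masking everything outside each wave's delineated segments. The
reconstruction model is the per-sample linear lead transform

    y = A x + C

where `x` stacks the six input channels (P-masked from lead II, QRS-masked
from lead V3, T-masked from lead I, plus raw I, II, V3), `A` is the
outputs × inputs coefficient matrix and `C` an intercept vector, fitted by
minibatch SGD (with a closed-form least-squares fit as the exact anchor).
The masked channels let one linear map apply *wave-specific* gains, which
a transform on raw leads cannot: different waves arrive at the electrodes
with different relative amplitudes, and raw per-sample inputs carry no
wave identity.

The package is aimed at biomedical-signal researchers who want to study
this augmentation end to end without access to large ECG archives: a
synthetic 12-lead generator with exact, provable wave supports and known
(optionally wave-specific) lead mixing makes every pipeline testable and
the masking advantage verifiable by construction.

## What is included

* **io_preprocess** — CSV / WFDB (format 16) / HDF5 readers and writers,
  metadata-criteria record selection (normal, no monitored rhythm
  condition, no duplicate patient, no blank lead), trimming, polyphase
  rational resampling, zero-phase Butterworth denoising.
* **delineation** — Pan–Tompkins-style R-peak detection and P/QRS/T
  on/offset delineation using only leads I, II, V3, fused across leads by
  median; import/export of a 0-based fiducial CSV dialect.
* **wave_masking** — `mask_wave()` (zero outside half-open segments) and
  `build_augmented_input()` (the fixed six-channel stack).
* **reconstruction** — `fit_ols()`, `fit_sgd()`, `predict()`,
  `derive_limb_leads()`, and `make_pipeline()` for the five studied
  variants (`p1` = I,II,V2; `p2` = I,II,V3; `wmlr` = augmented; `lstm`,
  `ffn` = reduced-scale deep baselines).
* **evaluation** — per-record per-lead Pearson r and RMSE, patient-wise
  k-fold cross-validation, aggregate/box-plot tables, paired t-tests.
* **synthetic_data** — sum-of-Gaussians cohort generator with exact
  fiducials, global or per-wave lead mixing, configurable SNR.
* **cli** — `inst/cli/wmlr.R` with `simulate` / `run` / `compare`
  subcommands, YAML/JSON configs and reproducible manifests.

## Worked example

```r
library(wmlr)

# a 15-patient cohort whose reconstructed leads carry wave-specific gains
cohort <- generate_cohort(synth_config(n_patients = 15,
                                       mixing_mode = "per_wave",
                                       disparity = 0.2,
                                       noise_snr_db = 20, seed = 22))
entries <- lapply(cohort$entries, function(e)
  list(record = e$record, fiducials = e$fiducials))
folds <- make_patient_folds(vapply(entries, function(e)
  e$record$patient_id, character(1)), k = 5, seed = 42)

rep_p2 <- cross_validate(make_pipeline("p2", fitter = "ols"), entries, folds)
rep_wm <- cross_validate(make_pipeline("wmlr", fitter = "ols"), entries, folds)
c(p2 = mean(rep_p2$per_record$r), wmlr = mean(rep_wm$per_record$r))
#>        p2      wmlr
#> 0.9786907 0.9933707
```

Both pipelines are cross-validated patient-wise (no patient appears in
both the training and test side of a fold). The raw-lead transform stalls
near r ≈ 0.979 because one linear map cannot express per-wave gains; the
wave-masked transform reaches r ≈ 0.993, the residual being the injected
20 dB channel noise. `summarize_report(rep_wm)` prints the per-lead
median/mean/SD tables and box-plot summaries;
`compare_reports(rep_wm, rep_p2)` runs the per-lead paired t-tests.

The same comparison from the shell:

```sh
Rscript inst/cli/wmlr.R simulate --config sim.yaml --out cohort/
Rscript inst/cli/wmlr.R run      --config run.yaml --out report/
Rscript inst/cli/wmlr.R compare  --a report_wmlr/ --b report_p2/ --out cmp.csv
```

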