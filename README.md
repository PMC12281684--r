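# petdist

Lesion-to-prostate distance features from PSMA-PET, with the survival
analysis that makes them prognostic.

## What this is for

After radical prostatectomy, biochemical recurrence (BCR: serum PSA rising
above 0.2 ng/mL) affects a large fraction of prostate-cancer patients.
Presurgical ⁶⁸Ga-PSMA-11 PET shows every PSMA-avid lesion in the body, and
beyond the conventional uptake measures there is prognostic signal in
*where* those lesions are. `petdist` is for imaging scientists and
biostatisticians who want to extract and model that signal. From an SUV
volume, a prostate mask and optional lesion seed points it computes, per
patient:

- **SUVmax** — the maximum standardized uptake value of the primary
  (intraprostatic) lesion, with SUV = c·w/A (activity concentration ×
  body weight / injected dose);
- **PMTV** — the primary lesion's metabolic tumor volume (cm³) at a
  40%-of-SUVmax segmentation threshold;
- **Dmax** — max over lesions of the Euclidean distance ‖x̄ᵢ − p‖₂ between
  the lesion centroid x̄ᵢ and the geometric prostate center p (cm);
- **Dtotal** — the sum of those distances (cm).

The survival stage then reproduces the standard workflow: dichotomization
at fixed (or data-driven) cutoffs, Kaplan–Meier curves and log-rank tests,
univariable and multivariable Cox proportional-hazards models
(S(t|x) = S₀(t)^exp(βᵀx), Efron ties) with Harrell's C-index, and a
three-tier risk stratification combining PMTV and Dmax. Synthetic phantoms
and cohort simulators with exact ground truth make every stage testable
without patient data.

## Worked example

Build a phantom with a primary tumor inside the prostate and two distant
metastases, run the imaging pipeline, then analyze a simulated cohort:

```r
library(petdist)

spec <- phantom_spec(
  shape = c(100, 100, 70), spacing = 2,
  prostate_center = c(100, 100, 70), prostate_semiaxes = c(24, 20, 18),
  lesions = data.frame(x = c(104, 40, 150), y = c(100, 60, 160),
                       z = c(70, 70, 50), sigma = c(10, 6, 6),
                       peak = c(15, 7, 9)),
  seed = 42)
ph  <- generate_phantom(spec)
seg <- segment_lesions(ph$pet, seeds = ph$truth$seeds, mode = "per_seed")
seg
#> Lesion label map (per_seed, fraction 0.40): 3 lesions, 1823 voxels
compute_features(seg, ph$pet, ph$prostate, patient_id = "PH-001")
#>   patient_id suvmax pmtv_cm3  dmax_cm dtotal_cm n_lesions metastasis
#> 1     PH-001     15   10.472 8.062258  15.67336         3       TRUE
```

The primary lesion (Gaussian, peak SUV 15, σ = 10 mm) yields SUVmax 15 and
PMTV 10.47 cm³ — the 40% isocontour of that Gaussian is analytically a
10.39 cm³ ball, so the voxelized volume is within 1%. The farthest
metastasis sits 8.06 cm from the prostate center (Dmax) and the three
distances sum to 15.67 cm (Dtotal), matching the planted geometry exactly.

```r
co  <- generate_cohort(cohort_params(n = 400, seed = 7))
rep <- run_survival(co$features, co$outcomes)
rep
#> Survival report: n = 400, events = 143
#> ...
#> model1 (C-index 0.66)
#> Cox PH fit (efron ties): n = 400, events = 143, C-index = 0.657
#>            term   coef       HR [95% CI]       p
#>  psa_ng_ml_high -0.085 0.92 [0.63, 1.34] 6.6e-01
#>   pmtv_cm3_high  1.160 3.20 [2.29, 4.48] 9.8e-12
#>    dmax_cm_high  0.595 1.81 [1.29, 2.55] 6.5e-04
#> Risk groups (low/intermediate/high):  136 / 204 / 60
#> Overall log-rank: chi2 = 68.79, p = 1.2e-15
```

The simulator plants hazard ratios of 2.5 (PMTV-high) and 2.0 (Dmax-high);
the multivariable fit recovers effects of that order (here 3.20 and 1.81 at
n = 400 — sampling noise at this size; recovery tightens at n = 1000), and
the PMTV/Dmax risk tiers separate sharply on the log-rank test. For
file-based cohorts, `pipeline_config()` + `run_extract()` drive the same
computation from NIfTI volumes and CSV metadata, with per-patient failures
skipped and logged rather than fatal.

## Documentation

The methods vignette (`vignettes/petdist-methods.Rmd`) documents the
models, every tunable parameter with units and defaults, the numerical
conventions (thresholding, connectivity, tie-breaking, dichotomization
boundaries), the design of the synthetic generators and what passing tests
do and do not establish about clinical data.
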