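# oemri — oxygen-enhanced MRI analysis of lung density and function

`oemri` is an R package for the quantitative analysis of oxygen-enhanced MRI
(OE-MRI) of the lung, together with a digital-phantom simulator that makes
every stage of the analysis testable without access to scanner data. It is
aimed at preclinical imaging scientists working with inversion-recovery
ultrashort echo-time (UTE) protocols, in particular two-gas-state studies
(air vs 100% O2) of emphysema models in the mouse.

## The method

During each gas state the scanner acquires one magnitude image per inversion
time TI. The pixel signal follows the three-parameter inversion-recovery
model

    S(TI) = | S0 · (1 − B · exp(−R1 · TI)) |

with `S0` the signal at full relaxation, `R1 = 1/T1` the longitudinal
relaxation rate and `B` the inversion-efficiency factor (2 for a perfect
inversion). Fitting this model pixel-wise in each gas state yields:

* **lung density**: `S0_air`, the air-state S0, a proxy for relative lung
  proton density;
* **oxygen uptake**: `ΔR1 = R1_O2 − R1_air` (s⁻¹), driven by oxygen
  dissolved in tissue and plasma;
* **oxygen delivery**: `ΔR2* = ln(S0_air / S0_O2) / TE` (ms⁻¹), driven by
  gaseous oxygen in the alveoli shortening T2* and attenuating the
  oxygen-state S0 at the echo time TE.

On top of the maps the package provides:

* whole-lung ROI summaries (mean and SD of the five parameters per animal)
  and two-sample t-tests between groups, at the level of the animal means
  (global function) and of the animal SDs (heterogeneity);
* equal-count binning of the pooled lung pixels of all animals into 20
  density strata (~1,000 pixels each), with per-bin per-group means — the
  regional density-vs-function analysis — and the same machinery binned on
  ΔR2*;
* an animal-level permutation test (labels permuted among animals, all
  pixels of an animal moving together, N = 10,000) for per-bin group
  differences, and an animal bootstrap for the SDs of the binned curves.

The phantom generator produces two-group studies (default 9 control vs 8
elastase-challenged animals) whose per-pixel density, R1, ΔR1 and ΔR2*
fields reproduce the group means, within-animal SDs, the monotone
density→uptake relationship and the linear uptake–delivery coupling of a
murine emphysema study, so recovery of all downstream statistics can be
verified against known truth.

## Worked example

```r
library(oemri)

## ground truth and a simulated two-gas-state series for one control animal
gt     <- make_phantom(phantom_spec("control", seed = 1))
series <- simulate_signal(gt, acquisition_protocol(), seed = 2)
maps   <- fit_maps(series)
summarize_roi(maps)[c("n_valid_pixels", "s0_air_mean", "r1_air_mean",
                      "delta_r1_mean", "delta_r2star_mean")]
#>   n_valid_pixels s0_air_mean r1_air_mean delta_r1_mean delta_r2star_mean
#> 1            875    3.420064   0.5489127    0.02208643        0.06587648
```

875 of ~1,200 lung pixels pass fit validity in both gas states; the ROI
means recover the generating values (density 3.29 a.u., R1_air 0.557 s⁻¹,
ΔR1 0.024 s⁻¹, ΔR2* 0.071 ms⁻¹) up to noise and the valid-pixel selection
discussed in the vignette.

```r
## a full noiseless study: density-binned oxygen uptake, group contrast
st   <- make_study(study_spec(master_seed = 1), signals = FALSE)
px   <- build_pixel_table(st)
bins <- assign_bins(px$s0_air, 20)
bm   <- bin_group_means(px, bins, "delta_r1")
perm <- permutation_test_bins(px, bins, "delta_r1",
                              n_permutations = 10000, seed = 3)
cbind(bm[c("bin", "n_pixels", "mean_control", "mean_challenged")],
      p = perm$p_value)
#>   bin n_pixels mean_control mean_challenged      p
#> 1   1     1027      -0.0651         -0.1507 0.0005
#> 2   2     1027      -0.0552         -0.0829 0.0245
#> ...
#> 19  19    1026       0.0797          0.1971 0.0000
#> 20  20    1026       0.0973          0.2661 0.0000
```

The challenged group shows lower oxygen uptake than control in the
lowest-density bins (destroyed, poorly perfused parenchyma) and higher
uptake in the highest-density bins (compensating healthy tissue), with the
permutation test localising the significant bins at both ends — the
characteristic regional signature that the global ΔR1 comparison misses.

The full pipeline (simulate → fit → roi → bins → stats, with all artifacts
written as NIfTI/CSV/JSON into a run directory) is driven by
`run_pipeline(pipeline_config(...), "run_dir")`, or from a shell via the
thin wrapper `inst/cli/oemri.R`.

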