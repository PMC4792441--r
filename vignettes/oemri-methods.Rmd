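---
title: "Models and methods behind oemri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oemri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the signal model, the synthetic study generator, the
statistical procedures and the numerical choices made in `oemri`, in enough
detail that a user can judge what a passing test suite does and does not
demonstrate about real scanner data.

## 1. Signal model and relaxometry

Magnitude inversion-recovery data are modelled pixel-wise as

$$S(\mathrm{TI}) = \left| S_0 \left(1 - B\, e^{-R_1 \cdot \mathrm{TI}}\right) \right|,$$

a three-parameter model with the signal at full relaxation $S_0$, the
longitudinal relaxation rate $R_1$ and a dimensionless inversion-efficiency
factor $B$ ($B = 2$ for a perfect global inversion, $B = 1$ for saturation).
The fit operates on the folded magnitude curve directly; no polarity
restoration is attempted. With only seven TI samples a sign-recovery
heuristic would itself be a noise-sensitive estimator, whereas the folded
model is well-defined for every parameter combination.

Units are fixed package-wide: TI and TE in ms, $R_1$ and $\Delta R_1$
reported in s⁻¹ (the fit converts internally; a protocol declared in seconds
gives identical output, which is pinned by a unit test), $\Delta R_2^*$ in
ms⁻¹.

**Derived maps.** Oxygen uptake is $\Delta R_1 = R_{1,\mathrm{O_2}} -
R_{1,\mathrm{air}}$. Oxygen delivery is $\Delta R_2^* =
\ln(S_{0,\mathrm{air}} / S_{0,\mathrm{O_2}})/\mathrm{TE}$, which assumes TE
is short enough that oxygen in the *air* state leaves $S_{0,\mathrm{air}}$
essentially unattenuated; the simulator enforces this assumption by
construction (attenuation is applied only to the oxygen state), and the
pipeline reports the global $S_{\mathrm{O_2}}/S_{\mathrm{air}}$ ratio
(≈ 0.96 under the default templates) as the standard validity check.
Negative $\Delta R_2^*$ values (oxygen-state signal *gain*) are retained and
flagged, not censored.

**Optimisation.** For $S_0 > 0$ the model is linear in $S_0$, so $S_0$ is
profiled out analytically and the optimiser works on $(B, R_1)$ only, with
`stats::nlminb` under box constraints (defaults $R_1 \in [0.01, 20]$ s⁻¹,
$B \in [0, 2.1]$, $S_0 \in (0, \infty)$). Starts are the canonical
initialisation ($B = 2$, $R_1$ from the null-point heuristic
$\mathrm{TI}_\mathrm{null} = \ln 2 / R_1$ at the minimum-signal TI) plus the
best points of a coarse data-independent $(B, R_1)$ objective grid, greedily
thinned so restarts sit in distinct basins (`n_multistart = 4` by default).
The lowest residual wins; exact ties break to the lower $R_1$. The
convergence tolerance (`rel.tol = 1e-12`) is tight because the noiseless
oracle tests require recovery to $10^{-4}$ relative error; nlminb's
"singular convergence" return — a flat-valley stop at the optimum, common
for this model — is accepted, "false convergence" is not.

**Validity policy.** A pixel's fit is invalid when the optimiser fails, a
parameter lands on a bound, or the residual exceeds the configured ceiling.
At-bound fits are flagged rather than clipped so the delta maps never mix
converged and saturated estimates. Delta maps exist only where *both* gas
states fit validly. All-zero or constant signals are flagged invalid
immediately; negative or non-finite inputs are rejected as errors.

**A consequence worth knowing.** With $B_{\mathrm{true}} = 2$ and the
default bound at 2.1, the sampling distribution of $\hat B$ (sd ≈ 0.08 at
the control mean density, ≈ 0.17 in low-density pixels at the default noise
level) places 10–25% of pixels per gas state on the bound. Exclusion is
therefore density-dependent, and pooled valid-pixel means of density and
$\Delta R_1$ shift upward relative to the full-mask ground truth. The
per-animal fit-failure rates are logged by the pipeline precisely so this
selection is visible; the recovery tests that compare fitted to generating
values do so over the valid pixels (estimation bias, which is small) and the
limitation is restated in §5.

## 2. The synthetic study generator

One synthetic animal is a pair of elliptical "lungs" (~1,200 pixels on a
64×64 grid by default) carrying four spatially correlated parameter fields:

* `s0_air` — density proxy; control mean 3.29 a.u. (SD 0.62), challenged
  2.90 (0.66): emphysema lowers and broadens the density distribution.
* `r1_air` — baseline R1; 0.557 s⁻¹ (0.067) vs 0.549 (0.081), generated
  independently of density because baseline R1 shows no density dependence.
* `delta_r1` — uptake; means 0.024 vs 0.025 s⁻¹ (SDs 0.094 vs 0.110),
  coupled to local density with slope 0.06 (control) / 0.16 (challenged)
  s⁻¹ per density unit plus an orthogonal residual field. The steeper
  challenged slope makes the per-bin uptake curves cross near pooled density
  ≈ 2.7: challenged pixels take up less oxygen than control in low-density
  regions and more in high-density regions, with a wider overall range.
* `delta_r2star` — delivery; means 0.071 vs 0.090 ms⁻¹ (SDs 0.205 vs
  0.267), generated from `delta_r1` through the coupling slopes 0.47 / 0.42
  s⁻¹ per ms⁻¹, chosen once to give a within-group uptake–delivery
  correlation of 0.98 (the "excellent correlation" regime) while matching
  the marginal SDs exactly.

Fields are built by Gaussian-smoothing white noise (correlation length 3
pixels — patchy heterogeneity without a tissue model) and standardising to
the template mean/SD exactly over the mask; residual fields are
orthogonalised against their predictors so marginal SDs hit their targets
exactly. Consequently sample moments match templates to within floating
point, not merely in expectation. Rare positivity clips keep
$R_{1,\mathrm{O_2}} > 0$.

A study draws per-animal templates by jittering the four group means with
between-animal SDs taken from the group-level table of the emulated
experiment (e.g. density 0.16 control / 0.23 challenged), then generates
each animal's phantom and, optionally, its noisy image series. All
randomness derives from one master seed; identical specs are bit-identical.

**Forward simulation.** Noiseless signals follow the model of §1 with
$R_{1,\mathrm{O_2}} = R_{1,\mathrm{air}} + \Delta R_1$ and
$S_{0,\mathrm{O_2}} = S_{0,\mathrm{air}} e^{-\Delta R_2^* \cdot
\mathrm{TE}}$. At the longest default TI (6000 ms) the control-lung signal
has recovered only to ~93% of $S_0$, so the simulator never treats the last
image as fully relaxed — $S_0$ must be estimated by the fit. Noise is
Gaussian on the magnitude, truncated at zero (adequate at the default SNR of
~20 at the control mean density, i.e. σ = 0.1645 signal units), with a
Rician option; outside the mask only background noise is present.

**What the generator does not emulate.** Radial k-space sampling and
gridding/streak artifacts, respiratory motion, atelectasis, partial-volume
vessels, B1 inhomogeneity, and segment-ordering effects of the segmented
UTE readout. Two statistical simplifications matter when comparing numbers
to the emulated study: (i) only the group *means* are jittered between
animals, so the between-animal spread of the within-animal SDs is not
reproduced — heterogeneity contrasts are sharper in simulation than in
reality; (ii) the printed within-animal SDs of the real study are SDs of
*fitted* maps (containing that study's estimation noise), whereas here they
parameterise the ground-truth fields, so refitted simulated maps carry
estimation noise *on top* (e.g. within-animal $\Delta R_2^*$ SD ≈ 0.28
fitted vs 0.205 generated).

## 3. ROI statistics and group comparisons

Per animal, the mean and sample SD (n−1 denominator, fixed by a unit test)
of the five parameters are computed over valid in-mask pixels. Group
comparisons are two-tailed two-sample t-tests on the per-animal statistic —
means for global function, SDs for heterogeneity. Welch's form is the
default because the emulated disease group has visibly larger variances; a
pooled-variance option exists. The t statistic is oriented challenged minus
control. When both groups have zero variance (possible with the exact
moment-matching generator) the comparison degenerates deterministically:
equal means give $t = 0, p = 1$; unequal means give $t = \pm\infty, p = 0$.
Single-group designs and groups of one animal are refused with an explicit
error. No multiple-testing correction is applied across the five parameters.

## 4. Bin analysis and resampling inference

**Equal-count bins.** The pooled valid pixels of all animals and both
groups are ranked on the binning variable (density by default, delivery as
the second mode) and split into 20 bins whose counts differ by at most one;
when the count is not divisible the lowest bins take the extra records. Ties
break by record order through a stable sort, so the assignment is
deterministic even for constant input. Bin edges (midpoints between adjacent
bins' extreme values) are reported for presentation, but membership is
defined by rank, not by edges. Pooled edges are the default because per-bin
group differences are only well-defined on a shared stratification; a
per-group quantile mode exists for presentation-style curves.

**Permutation test.** Bin edges and observed per-bin group differences are
computed once from the unpermuted data; then group labels are permuted among
the *animals* (N = 10,000 random relabelings by default — the assignment
space is far too large to enumerate at n = 17), all pixels of an animal
moving together, which respects the within-animal correlation of pixels. Per
bin, $p$ is the fraction of permutations whose absolute mean difference
strictly exceeds the observed one — no +1 smoothing, so the resolution is
$1/N$ and the minimum reportable p is 0. The test is two-tailed by
construction and invariant to which group is called first. Permutations in
which a bin loses all pixels of one group are dropped for that bin and the
effective count reported. Output tables flag bins with $p < 0.1$, the
marking convention used for binned-curve plots. The test suite checks the
Monte-Carlo p against exhaustive enumeration on a 3-vs-2 toy design and the
false-positive rate against the nominal 5% level on 500 null studies.

**Bootstrap.** Animals are resampled with replacement within each group
(2,000 replicates by default — the replicate count is a package choice, not
a property of the emulated study); per replicate the per-bin group means are
recomputed against the fixed edges, and the SD over replicates estimates the
between-animal variability of the binned curves. Resampling animals rather
than pixels keeps the exchangeability unit consistent with the permutation
test; pixel-level resampling would understate the SDs badly because pixels
within an animal are correlated. Both procedures are bit-reproducible given
their seed, implemented on per-animal-per-bin sufficient statistics so a
permutation costs a 17-element weighted sum per bin.

## 5. Known limitations

* **Valid-pixel selection.** The at-bound flagging policy plus the tight
  physical bound on B excludes 10–25% of pixels per gas state at the default
  SNR, preferentially at low density. Pooled means over valid pixels are
  therefore shifted upward relative to the full lung. Comparisons of fitted
  versus generating values in the tests are made over valid pixels, where
  the estimation bias of the group-mean $\Delta R_1$ is below 10%.
* **Exact moment matching.** Because phantom fields match template moments
  exactly, per-animal SDs carry no sampling noise; heterogeneity t-tests on
  simulated data are more powerful than they would be on real data.
* **No reconstruction chain.** Images are simulated in image space; nothing
  about radial reconstruction, its noise correlations, or its artifacts is
  represented.
* **p-value resolution.** With strict-inequality counting the permutation p
  can be exactly 0; readers should interpret p = 0 as p < 1/N.

## 6. Problem sizes used by the test suite

The suite favours small grids (24×24, ~120-pixel masks) wherever only the
statistical machinery is exercised, and the full default geometry (64×64,
~1,200-pixel masks) where the claim concerns the default study: the null
calibrations use 500 simulated studies, the heterogeneity-pattern check 100
default studies, the noisy-recovery checks a 9-animal study at default SNR,
and the noiseless relaxometry oracle a 125-point parameter grid. These sizes
are the package's choice of a desk-scale experiment: large enough for
binomial tolerances of a few percentage points, small enough to run
routinely.
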