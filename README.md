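# glymphdti

Glymphatic indices from single-shell diffusion MRI, with Bayesian
model-averaged group comparison.

The glymphatic system is the brain's proposed waste-clearance pathway: CSF
enters along periarterial spaces, exchanges with interstitial fluid through
astrocytic AQP-4 channels, and drains along perivenous spaces. Two
diffusion-MRI quantities serve as indirect, non-invasive proxies of this
system in white matter, and this package computes both from a preprocessed
single-shell DWI acquisition (b = 0 plus one shell, e.g. 32 directions at
b = 1000 s/mm²):

* **Free-water (FW) fraction** — the per-voxel fraction *f* of an isotropic
  compartment with fixed diffusivity d_w = 3.0 × 10⁻³ mm²/s in the
  bi-tensor model

  S_q = s₀ [ (1 − f) exp(−b_q gᵀDg) + f exp(−b_q d_w) ],

  estimated by variable projection with spatial likelihood pooling, and
  summarized as the mean over a white-matter skeleton (FA > 0.2, medial
  surface) with lesions excluded. Elevated white-matter FW is read as
  stagnation of interstitial fluid drainage.

* **DTI-ALPS index** — from the single-tensor axis diffusivities in 5 mm
  spherical ROIs placed in projection fibers (superior corona radiata,
  principal axis z) and association fibers (superior longitudinal
  fasciculus, principal axis y) at the level of the lateral-ventricle body,

  ALPS = mean(Dxxproj, Dxxassoc) / mean(Dyyproj, Dzzassoc),

  averaged over hemispheres, lesions excluded. The x axis is the
  perivascular axis of the deep medullary veins; an index near 1 means no
  preferential perivascular diffusion.

Group differences (e.g. MS vs NMOSD) adjusted for age and EDSS are tested
by a **Bayesian model-averaged ANCOVA**: all 8 additive models over
{age, EDSS, group} with uniform prior 1/8, Jeffreys–Zellner–Siow
mixture-of-g Bayes factors per model, posterior model probabilities, BF_M,
and per-predictor inclusion Bayes factors — implemented in the package and
verified against independent quadrature oracles.

A synthetic phantom/cohort generator with exact ground truth (two oriented
fiber slabs, free-water compartment, lesions, Rician noise, clinical
covariate structure with groups of 42 and 21) stands in for patient data,
so the entire pipeline is testable offline. The package is aimed at
neuroimaging researchers who want a transparent, tested reference
implementation of these indices and their Bayesian group analysis.

## Worked example

```r
library(glymphdti)

# a study-like phantom: 40x40x20 voxels at 2 mm, b0 + 32 directions at
# b = 1000, two fiber slabs whose diffusivities imply ALPS = 2.0 exactly,
# 10% free water in the slabs, Rician noise at SNR 30
ph <- build_phantom(phantom_spec(seed = 1))

tsnr(ph$dwi)
#> <qc_report> tSNR 9.07 over 32000 voxels (shell volumes), cutoff 6.47: PASS

tm <- fit_tensor(ph$dwi)                     # WLS single-tensor fit
compute_alps(tm, ph$truth$roi_spec, ph$truth$lesion_mask)
#> <alps_result> left 1.8461, right 1.8417, mean 1.8439
```

The measured ALPS (1.84) sits below the analytic tissue value (2.00)
because the plain tensor fit is contaminated by the 10% free-water
compartment — exactly the effect the FW fit quantifies:

```r
fw <- fit_fw(ph$dwi)                         # bi-tensor free-water fit
sk <- wm_skeleton(tm)
mean_fw_on_skeleton(fw, sk, ph$truth$lesion_mask)
#> FW index 0.1361 over 2000 skeleton voxels
```

Cohort-level inference on a simulated null cohort (42 MS / 21 NMOSD, zero
direct group effect, age and EDSS distributions as in a real
neuroinflammatory clinic):

```r
tab <- simulate_cohort(cohort_spec(seed = 1))
res <- run_bayes_ancova(tab, "fw")
res
#> Bayesian model-averaged ANCOVA  (dv = fw, n = 63)
#>
#> Model                          P(M)       BF10     P(M|D)       BF_M
#> age                           0.125       1043      0.357      3.882
#> age + group                   0.125      840.4      0.288      2.825
#> group                         0.125        396      0.136      1.097
#> age + edss                    0.125      316.1      0.108     0.8489
#> age + edss + group            0.125      229.7      0.079     0.5972
#> edss + group                  0.125      94.31      0.032     0.2334
#> edss                          0.125      2.376      0.001   0.005696
#> null                          0.125          1      0.000   0.002396
#>
#> Inclusion Bayes factors (across all models / matched models):
#>   age           4.919      4.919
#>   edss         0.2818     0.2818
#>   group         1.146      1.146
```

Age carries real signal in this cohort (it both differs between groups and
drives the outcome), so age models dominate; the group inclusion BF of 1.15
is inconclusive — the direct group effect is zero, but models without age
absorb the age-confounded group difference. `tidy(res)` returns the model
table as a tibble, `glance(res)` a one-row summary, and `autoplot(res)`
plots the posterior model probabilities. The end-to-end driver
(`run_pipeline()`) chains QC → tensor → FW → ALPS → both ANCOVAs over a
simulated or file-based cohort, deterministically for a fixed seed; a thin
command-line wrapper lives at `inst/cli/glymphdti.R`
(`simulate | qc | fit-dti | fit-fw | alps | bayes-ancova | run`).

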