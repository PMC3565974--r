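# discmech

Quantitative-MRI and compressive-biomechanics analysis of intervertebral
discs, built around one question: how much of a disc's mechanical state —
Young's modulus E, zero-strain aggregate modulus H_A0, and the hydraulic
permeabilities k_r (radial), k_0 (zero-strain axial) and k_a (directly
measured) — can be predicted from five imaging biomarkers (T1, T2,
magnetization transfer ratio MTR, mean diffusivity ADC and fractional
anisotropy FA) via the linear model

    MP = a0 + a1·T1 + a2·T2 + a3·MTR + a4·ADC + a5·FA ?

It is aimed at researchers in cartilage/disc biomechanics and quantitative
MRI who want a reproducible, fully testable rendition of that analysis: the
study design is a 4-group digestion model (in-situ, 6 h, 18 h, 24 h trypsin)
× 2 regions (nucleus pulposus, annulus fibrosus), n = 15 per group.

The package contains five layers, each pairing a seeded generator with the
estimator that inverts it:

| layer | generators | estimators |
|---|---|---|
| qMRI | `simulate_ir_series`, `simulate_echo_series`, `simulate_mt_pair`, `simulate_dwi_series`, `simulate_phantom`, `add_rician_noise` | `fit_t1`, `fit_t2`, `compute_mtr`, `fit_diffusion_tensor`, `tensor_metrics`, `fit_voxelwise`, `roi_aggregate` |
| biomechanics | `simulate_unconfined_test`, `simulate_confined_test`, `simulate_darcy_test` | `fit_unconfined`, `fit_confined`, `darcy_permeability`, `detect_equilibrium` |
| forward models | `confined_forward_linear`, `confined_forward_nonlinear` (strain-dependent H_A(ε)=H_A0·e^(βε), k(ε)=k_0·e^(Mε)), `unconfined_forward` (biphasic radial flow + viscoelastic overlay) | — |
| cohort | `cohort_spec`, `simulate_cohort` | `one_way_anova`, `dunn_sidak_pairwise`, `fit_multilinear`, `regression_power`, `compute_vif`, `vif_eliminate`, `run_pca`, `correlation_circle`, `ward_cluster`, `natural_division` |
| pipeline | `study_config`, `run_study`, `analyze_cohort`, `write_report` + CSV/JSON/Newick I/O | — |

A thin command-line wrapper lives at `inst/cli/discmech.R`
(`Rscript discmech.R run --config study.yaml --out runs/`), but the package
functions are the primary interface. The methods vignette
(`vignettes/disc-mri-mechanics.Rmd`) documents every model, default and
numerical choice.

## Worked example

Round-trip the in-situ nucleus-pulposus ground truth through the MRI
simulators and fitters:

```r
library(discmech)

protocol <- acquisition_protocol()        # 15 TI 50-1900 ms, 10 TE, b = 1000
np <- tissue_truth(t1 = 1140, t2 = 124, mtr = 0.34,
                   tensor = tensor_from_md_fa(15.04e-4, 0.0803))

fit_t1(simulate_ir_series(np, protocol))$t1
#> [1] 1140
fit_t2(simulate_echo_series(np, protocol))$t2
#> [1] 124
m <- tensor_metrics(fit_diffusion_tensor(simulate_dwi_series(np, protocol)))
c(adc = m$adc * 1e4, fa = m$fa * 100)
#>   adc    fa
#> 15.04  8.03
```

`15.04` is the recovered mean diffusivity on the ×10⁻⁴ mm²/s reporting
scale and `8.03` the fractional anisotropy ×100 — both equal to the ground
truth, because fitter and generator share one forward model.

A full seeded study — cohort simulation, phantom fitting, group statistics,
regressions, PCA, Ward dendrograms with natural-division detection — is one
call:

```r
res <- run_study(study_config(seed = 1), out_dir = "runs")
res$analysis$NP$regressions[1:3, ]
#>   region   group response        r2          see     power  n
#> 1     NP in-situ        E 0.9969359 8.865893e-04 1.0000000 15
#> 2     NP in-situ      k_r 0.7301679 3.842056e+01 0.9694381 15
#> 3     NP in-situ     H_A0 0.9738207 3.096799e-02 1.0000000 15
```

(`r2` is the coefficient of determination of the Eq-above regression within
one group, `see` its standard error of estimate in the response's units,
`power` the overall-F power at α = 0.05.) The run directory contains every
table as plain CSV plus Newick dendrograms and a manifest; rerunning the
same config reproduces all files byte-identically.

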