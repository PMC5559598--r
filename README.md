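# dcmrf — dual-contrast magnetic resonance fingerprinting

`dcmrf` is an R toolkit for **DC-MRF**: quantifying two paramagnetic MRI
contrast agents *simultaneously* from co-registered T1/T2 maps. It is aimed
at quantitative-MRI and molecular-imaging researchers who want to prototype,
validate or teach the dual-agent quantification chain without scanner time:
every stage — relaxivity calibration, reference relaxometry, FISP-MRF
acquisition, dictionary matching, concentration mapping — runs in
simulation against digital phantoms with known ground truth.

## The model

A paramagnetic agent shortens relaxation in proportion to its
concentration. For two agents A (Gd role) and B (Mn role):

    1/T1 = 1/T1_0 + r1A·[A] + r1B·[B]
    1/T2 = 1/T2_0 + r2A·[A] + r2B·[B]

Because MRF measures T1 and T2 at once, these two equations solve per voxel
for the two concentrations:

    [A] = (ΔR2·r1B − ΔR1·r2B) / (r2A·r1B − r1A·r2B)
    [B] = (ΔR2 − r2A·[A]) / r2B

with ΔR1 = 1/T1 − 1/T1_0, ΔR2 = 1/T2 − 1/T2_0. The package implements this
forward model and closed-form inversion (`forwardRelaxation`,
`invertDualAgent`), OLS relaxivity calibration (`fitRelaxivity`),
inversion-recovery / CPMG relaxometry simulators with mono-exponential
fitting, an extended-phase-graph FISP-MRF engine with dictionary generation
and inner-product matching (`simulateFISP`, `buildDictionary`,
`matchMap`), a 17-vial digital phantom generator (`defaultPhantomSpec`,
`simulateMRFSeries`, `repeatStudy`), and the quantification head
(`concentrationMaps`, `roiStats`, `calibrationReport`, `compareVials`,
`runPipeline`). A thin CLI (`exec/dcmrf`) wraps the pipeline stages.

Units throughout: times ms, rates ms⁻¹, relaxivities mM⁻¹ms⁻¹,
concentrations mM (divide s⁻¹mM⁻¹ literature values by 1000).

## Worked example

Forward-model a Gd/Mn mixture at 60 MHz parameters and invert it:

```r
library(dcmrf)
water <- referenceBaseline("60MHz")           # T1_0 = 4250 ms, T2_0 = 2760 ms
gd <- referenceRelaxivities("Gd", "60MHz")    # r1 = 0.0040, r2 = 0.0048
mn <- referenceRelaxivities("Mn", "60MHz")    # r1 = 0.0054, r2 = 0.0652

tt <- forwardRelaxation(water, gd, mn, concA = 0.2, concB = 0.1)
tt
#>         T1       T2
#> 1 634.8021 127.5133

invertDualAgent(water, gd, mn, tt$T1, tt$T2)
#>   concA concB
#> 1   0.2   0.1
```

A 0.2 mM Gd + 0.1 mM Mn mixture shortens water's T1 from 4250 to ~635 ms
and T2 to ~128 ms; the closed-form inversion recovers both concentrations
exactly. A full in-silico study — 17-vial phantom, 3000-point FISP-MRF
acquisition, dictionary matching, per-agent concentration maps and
calibration report — is one call:

```r
res <- runPipeline(list(out_dir = "run1", seed = 1, noise_sd = 0.01))
res$calibration$A
#> CalibrationFit (n = 17): slope = 0.993777, intercept = 0.000339818, R^2 = 0.999848, p = 4.67e-30
res$calibration$B
#> CalibrationFit (n = 17): slope = 0.997076, intercept = -0.000227393, R^2 = 0.999903, p = 1.67e-31
```

The slope near 1 and R² near 1 say the estimated Gd concentrations track
the ground truth across all 17 vials; the residual bias is set by the
dictionary's grid quantization (see the methods vignette,
`vignettes/dcmrf-methods.Rmd`).

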