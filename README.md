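# cardioqsm

Quantitative susceptibility mapping (QSM) of the heart from multi-echo
gradient-echo MRI, in R.

Hemorrhagic reperfusion injury after myocardial infarction deposits iron in
the infarct.  Iron is paramagnetic: it raises the local magnetic
susceptibility (Δχ, in ppm relative to water), perturbs the B0 field sensed
by nearby protons, and shortens T2*.  QSM recovers Δχ voxelwise from the MRI
signal phase and so gives an iron-specific contrast where T2*-weighted
magnitude imaging is confounded by coexisting edema and fibrosis.  This
package is for imaging scientists who want a fully tested, scriptable
cardiac QSM chain with a ground-truth phantom for validation.

## What it implements

* **Forward model** — Fourier-domain dipole kernel `D = 1/3 − kz²/k²`
  (physical frequency units, oblique B0 supported, `D(0) = 0`), field
  simulation `Φ = F⁻¹ D F Δχ`, and the analytic magnetized-sphere oracle.
* **Field preparation** — temporal + quality-guided phase unwrapping,
  per-voxel magnitude²-weighted least-squares fit of
  `φ(TE) = φ0 + 2π f TE` (total field in ppm), magnitude-threshold tissue
  mask, per-voxel SNR weight `W`.
* **Background removal** — projection onto dipole fields (PDF): CG fit of
  exterior susceptibility sources, subtracted inside the mask.
* **Dipole inversion** — morphology-enabled, TV-regularized:

      Δχ = argmin λ‖M G Δχ‖₁ + ‖W (F⁻¹ D F Δχ − Φ)‖₂²

  solved by IRLS (majorize–minimize) with warm-started conjugate gradients;
  `M` is a per-direction magnitude-edge mask, `G` the spatial gradient.
* **Relaxometry** — voxelwise two-parameter fit `S = A e^(−TE/T2*)`, R2* =
  1/T2*, relative-RMS error maps.
* **ROI analysis** — iso/hyper/hypo region classification on T2*-weighted
  images, remote-referencing of Δχ, FWHM infarct sizing, ROC curves with
  AUC (= pairwise concordance) and Youden-optimal operating points, tidy
  per-region statistics.
* **Synthetic cardiac phantom** — ellipsoidal myocardial shell with an
  endocardial infarct wedge (default +0.07 ppm, T2* 10 ms vs remote 30 ms),
  blood pool, optional air inclusion; 5 echoes at TE 3.3–16.1 ms, 3 T,
  seeded complex Gaussian noise; exact label-wise ground truth.

Everything is exposed both as S4 classes/functions and as a single
`runPipeline()` orchestrator with YAML configuration, NIfTI-1 volumes and
JSON provenance.  A thin CLI lives at `inst/scripts/qsm-pipeline.R`.

## Worked example

Simulate the default 96³ ex vivo-style phantom at SNR 40 and reconstruct it
end to end:

```r
library(cardioqsm)
res <- runPipeline(pipelineConfig())   # ~6 min on one CPU

lab <- res$truth@labels                 # 0 bg, 1 remote, 2 infarct, 3 blood
m   <- voxelValues(res$mask) != 0
chi <- voxelValues(res$chiReferenced)   # ppm, referenced to remote

mean(chi[lab == 2 & m]) - mean(chi[lab == 1 & m])
#> [1] 0.06702897          # recovered infarct − remote Δχ; truth is 0.07 ppm

res$roc
#> RocResult: AUC = 0.9835, ...   # recovered χ separates infarct from remote

res$stats[1:4, c("map", "region", "n", "mean", "sd")]
#>       map  region     n          mean         sd
#> 1 chi_ppm  remote 29363 -9.464251e-20 0.01645279
#> 2 chi_ppm   hyper  2323  8.299634e-04 0.01682638
#> 3 chi_ppm    hypo  2898  5.507355e-02 0.03563486
#> 4 chi_ppm infarct  5221  3.093874e-02 0.03946505
```

Reading: the recovered infarct−remote susceptibility difference is
0.067 ppm against a simulated truth of 0.07 ppm (−4%); remote myocardium is
centered on 0 by construction (referencing) with a noise floor of
~0.016 ppm SD; the T2*-hypointense core — where the simulated hemorrhagic
iron sits — carries the paramagnetic shift (+0.055 ppm), while the
hyperintense rim stays near remote values, and the ROC AUC of 0.98 says the
recovered map classifies infarct vs remote voxels almost perfectly at this
SNR.  `res$t2sFit` recovers the regional T2* (medians 30.1 ms remote,
10.0 ms infarct vs truths 30/10).

Write NIfTI + CSV + provenance by adding `outDir = "out/"`, or from a shell:

```sh
Rscript inst/scripts/qsm-pipeline.R all --config cfg.yaml --out out/
```

## Layout

```
R/                   S4 classes, generics and the eight analysis modules
tests/testthat/      unit + property + acceptance suites (fixtures built in code)
vignettes/           methods vignette: models, parameter rationale, limitations
scripts/acceptance.R headline-quantity reproduction script
inst/scripts/        command-line wrapper
```

See `vignettes/cardiac-qsm-methods.Rmd` for the model derivations, the
L-curve behind the default λ = 1e-4, the projection-onto-dipole-fields
boundary/thin-shell analysis, and what phantom-based validation does and
does not demonstrate about in vivo data.
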