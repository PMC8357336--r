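# domscope

Forward modelling and analysis for **diffuse optical microscopy (DOM)** —
structured-illumination reflectance imaging of epithelium through a
contact fiber bundle, in the sub-diffusive spatial-frequency regime
(f ≈ 2–20 mm⁻¹).

A DOM instrument projects sinusoidal patterns through an angle-polished
imaging bundle, captures three phase-shifted reflectance images per
spatial frequency, and demodulates them into a DC (mean) and an AC
(modulation-amplitude) image. Because lateral modulation washes out with
depth, the AC image at high spatial frequency is dominated by the
superficial epithelium even though the raw signal is ~90% deep diffuse
background; the frequency dependence of the AC reflectance is therefore a
depth-resolved probe of epithelial backscattering, and the ratio
R(9 mm⁻¹)/R(3 mm⁻¹) a candidate diagnostic for high-grade squamous
dysplasia.

The package implements, for this class of instrument:

* **Monte Carlo photon transport** in a semi-infinite turbid medium with
  oblique (20°) illumination refracted from the polished bundle
  (n = 1.60) into tissue (n = 1.38), hard 13.2° acceptance-cone detection,
  1-D binned exit positions, and the SFD reflectance
  `R(f) = Σₙ Bₙ exp(i 2π f xₙ) Δx` (Rcpp kernel; seeded, reproducible);
* **Scattering phase functions**: Henyey–Greenstein and the
  Gegenbauer-kernel (Reynolds–McCormick) family
  `p(μ) ∝ (1 + g_R² − 2 g_R μ)^−(σ+1)` with exact inverse-CDF sampling
  and quadrature anisotropy;
* **Penetration-depth quantiles** d50/d95 of the depth-resolved signal
  fraction `|R≤z(f)|/|R_tot(f)|`, with a noise-debiased amplitude
  estimator;
* the **demodulation pipeline**: dark referencing → 8×8 binning →
  order-2 Butterworth high-pass at f/4 → three-phase AC/DC demodulation
  → central-ROI averaging → normalisation to a scattering reference;
* a **synthetic generator** for fiber-bundle phase-image stacks and
  multi-case study cohorts with known ground truth;
* **diagnostics**: pixelwise backscattering-ratio maps, case-wise BS
  normalisation, boxplot summaries, and linear threshold classification
  (sensitivity over CIN2+CIN3, specificity over BS+CIN1).

## Worked example

Simulate the probe on epithelium-like optics and ask how deep the f = 3
and f = 15 mm⁻¹ signals originate:

```r
library(domscope)

pf  <- phase_function("reynolds-mccormick",
                      g_R = gr_for_anisotropy(0.9, sigma = 1.0),
                      sigma = 1.0)
med <- medium_from_musp(musp = 2, mua = 0.01, phase_function = pf)
res <- run_simulation(4e6, med, depth_cutoff = 1.2, seed = 500)

sfd_reflectance(res$bins, c(0, 3, 9, 15))
#>    f           Re            Im    amplitude
#> 1  0 0.0367022265  0.000000e+00 0.0367022265
#> 2  3 0.0009337232 -5.342428e-05 0.0009352503
#> 3  9 0.0004211416 -1.745442e-05 0.0004215032
#> 4 15 0.0003320014 -6.829341e-05 0.0003389526

# depth quantiles of the signal, median over 5 replicate simulations
penetration_depth_study(med, f = c(3, 15), n_photons = 6e6,
                        replicates = 5, seed = 500)
#>    f      d50       d95 n_detected
#> 1  3 64.61392 192.49263    1136007
#> 2 15 22.84502  55.06565    1136007
```

About 3.7% of launched photons are detected inside the acceptance cone
(`amplitude` at f = 0). The modulated amplitude falls steeply with
frequency, and half of the f = 15 mm⁻¹ signal originates in the top
~23 µm of tissue versus ~65 µm at f = 3 mm⁻¹ — the depth-sectioning
effect the instrument exploits.

The camera-side pipeline round-trips a synthetic scan:

```r
cfg    <- synth_scan_config()          # 900 µm field, 8-bit, AC/DC = 10%
set.seed(7)
stack  <- make_phase_stack(cfg, "9")   # three noisy phase images
dark   <- make_dark_stack(cfg, "9")
d      <- demodulate(bin_stack(subtract_dark(stack, dark), 8))
roi_mean(d$AC, d$mask, roi_diameter_um = 600, pitch_um = d$pitch_um)
#> [1] 17.40026
# generator truth 18 counts x 0.967 binning attenuation at f = 9/mm = 17.4
```

And a synthetic 13-case cohort is scored by the ratio diagnostic:

```r
study <- make_study(synth_study_config(), seed = 800)
cl    <- classify_linear(study, slope = 0.05, intercept = 0.45)
cl$confusion
#>           truth
#> called     HSIL LSIL/BS
#>   positive   24       0
#>   negative    2      52
round(c(sensitivity = cl$sensitivity, specificity = cl$specificity), 3)
#> sensitivity specificity
#>       0.923       1.000
```

(Numbers above are what the shown seeds print; the cohort generator's
group distributions are qualitative by design.)

## Command line

`exec/domscope` exposes the same operations as subcommands with YAML/JSON
configs and a JSON run manifest per output directory:

```sh
domscope simulate  --config sim.yaml  --seed 1 --out runs/sim
domscope depths    --config sim.yaml  --seed 1 --out runs/depths
domscope synth     --config study.yaml --seed 1 --out runs/study
domscope classify  --config line.yaml  --out runs/cls
```

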