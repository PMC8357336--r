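---
title: "Modelling depth-dependent epithelial backscattering with domscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling depth-dependent epithelial backscattering with domscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domscope)
```

## The measurement this package models

Structured-illumination reflectance imaging through a contact fiber bundle
("diffuse optical microscopy", DOM) projects sinusoidal intensity patterns
at spatial frequencies of a few cycles per millimetre onto tissue and
captures the backscattered light through the same bundle. Because a
laterally modulated pattern washes out with depth, the modulation
amplitude (AC) of the reflected pattern carries information predominantly
from the superficial epithelium, while the unmodulated mean (DC) is
dominated by deep diffuse backscattering — in cervical epithelium the
superficial contribution is only roughly 10% of the raw signal. Varying
the projection frequency between about 3 and 15 cycles/mm tunes the mean
signal origin between roughly one cell layer and the full epithelial
thickness, which makes the frequency dependence of the AC reflectance a
depth-resolved probe of epithelial scattering, and, because dysplastic
epithelium is more strongly backscattering near the surface, a candidate
diagnostic for high-grade squamous lesions.

`domscope` implements the computational core of such a system:

* a Monte Carlo forward model of the probe (module `mcsfd`), with the
  scattering phase functions it needs (module `phasefunc`);
* the camera-side demodulation pipeline (module `demod`);
* a synthetic image and cohort generator with known ground truth
  (module `synth`);
* the backscattering-ratio diagnostic and threshold classifier
  (module `diagnostics`);
* a thin command-line layer (`domscope_run()`, `exec/domscope`).

## Scattering phase functions

Sub-diffusive reflectance at high spatial frequency is sensitive to the
shape of the single-scattering phase function, not only to the reduced
scattering coefficient. The package therefore implements the
two-parameter Gegenbauer-kernel (Reynolds-McCormick) family
\[
p(\mu) = K\,(1 + g_R^2 - 2 g_R \mu)^{-(\sigma+1)},
\qquad
K = \frac{\sigma g_R (1-g_R^2)^{2\sigma}}
         {\pi\big[(1+g_R)^{2\sigma} - (1-g_R)^{2\sigma}\big]},
\]
which reduces to Henyey-Greenstein at \(\sigma = 1/2\) and develops
heavier forward *and* backward tails as \(\sigma\) grows — the regime
typical of epithelial cell scattering. Sampling uses the analytic inverse
CDF, so the sampler is exact; the anisotropy \(g = \langle\mu\rangle\) is
evaluated by adaptive quadrature (tolerance 1e-8).

The simulation studies in this package use \(\sigma \in \{1.0, 1.1,
1.2\}\). The second parameter is not fixed by that choice; we resolve it
by requiring an anisotropy of \(g \approx 0.9\), a standard value for
epithelium, via `gr_for_anisotropy()`. This is a genuine modelling choice:
published simulations of this instrument class do not state the full
parameter pairs, and penetration depths at fixed \(\mu_s'\) shift
noticeably with \(g\) (more forward-peaked functions push the signal
deeper). The choice is exposed as configuration everywhere.

## Monte Carlo transport model

Photons launch at the origin of a semi-infinite medium (z into the
tissue), refracted by Snell's law from the upper medium (n = 1.60, the
angle-polished bundle in contact) into tissue (n = 1.38) from a 20-degree
oblique illumination axis. Free paths are exponential with rate
\(\mu_s\); absorption (default \(\mu_a = 0.01\)/mm) is continuous weight
attenuation, applied lazily from the accumulated path length; scattering
angles come from the phase function with uniform azimuth; Russian
roulette (threshold 1e-4, survival 0.1) bounds photon lifetime. A photon
crossing z = 0 is refracted into the upper medium and *detected* if its
direction lies within 13.2 degrees of the fiber axis (the reverse of the
illumination axis) — a hard acceptance cone, which is how the instrument's
numerical aperture is conventionally approximated in simulation; the
near-Gaussian single-fiber acceptance profile is deliberately not
modelled. Fresnel reflection back into the medium at exit is not
simulated: the probe operates in index-matched contact (saline/mucus).

Detected exits are binned along the modulation axis
(\(\Delta x = 10\,\mu\)m over ±20 mm, comfortably finer than the Nyquist
requirement for \(f \le 20\)/mm; exits beyond the extent count as
undetected), giving the profile \(B_n\) per launched photon per bin
width. The SFD reflectance is its discrete Fourier transform
\[
R(f) = \sum_n B_n\, e^{i 2\pi f x_n}\, \Delta x ,
\]
a complex number whose modulus is the AC amplitude. Two invariants are
enforced by tests: energy bookkeeping (detected + rejected-exit +
absorbed + cutoff-killed + roulette-net = launched, to floating-point)
and equality of the binned DFT with a per-photon complex sum within the
binning error.

### Penetration-depth quantiles

Each record carries the photon's maximum depth. For a frequency f the
cumulative signal fraction at depth z is
\(|R_{\le z}(f)| / |R_{\mathrm{tot}}(f)|\), where \(R_{\le z}\) uses only
photons that never exceeded z — equivalent to rerunning the simulation
with an absorbing depth cap, the classical way of probing signal origin.
`d50` and `d95` are the first crossings of 0.5 and 0.95 on a 0-1000 um
grid (5 um steps, linear interpolation). Complex cancellation can make
the fraction locally non-monotonic; the first crossing is used. An
unweighted photon-count variant is available (`weighting = "photons"`)
but is frequency-independent and not the default.

Two numerical choices matter here:

* **Depth cutoff.** Depth studies terminate photons below a cap chosen
  per frequency: 1.2 mm (1.2x the deepest grid point) for f = 3/mm and
  0.4 mm (about six times the converged near-maximum depth) for
  f = 15/mm. Photons diving deeper contribute almost pure
  phase-incoherent noise to \(R\) at these frequencies while costing
  most of the CPU time; capping them is the standard signal-to-noise
  optimisation for sub-diffusive frequencies and makes the reported
  quantiles those of the depth-capped signal (a shift of a few
  micrometres at most, checked against a 1e8-photon uncapped-grid
  reference).
* **Replicate medians.** Even debiased, the `d95` first-crossing sits
  where the cumulative curve is nearly flat, so a single up-fluctuation of
  the total amplitude can delay the crossing by hundreds of micrometres:
  its sampling distribution has a heavy upper tail at any affordable
  photon count. Grid studies therefore run three independent replicates
  per condition and report the across-replicate median
  (`penetration_depth_study()`); a 1e8-photon reference run confirms the
  median sits on the converged value.
* **Noise debiasing.** With \(N_d\) detected photons the squared modulus
  of a complex Monte Carlo sum is inflated by \(\sum_j w_j^2\) in
  expectation (the incoherent Rayleigh power). At realistic photon counts
  this inflates \(|R_{\mathrm{tot}}(15/\mathrm{mm})|\) appreciably and
  biases the depth fractions downward, i.e. the quantiles upward, by
  tens of micrometres. `penetration_depths(debias = TRUE)` (the default)
  subtracts the accumulated incoherent power from both partial and total
  squared amplitudes before forming fractions; at high photon counts the
  plain and debiased estimates agree, at moderate counts only the
  debiased one is stable.

### Matching the scattering coefficient at high frequency

`match_mus_at_frequency()` adjusts \(\mu_s\) by bisection until
\(|R(20/\mathrm{mm})|\) reaches a target, the operation used to compare
phase-function families at matched high-frequency reflectance. Every
bisection evaluation reruns the simulation with the *same* seed (common
random numbers), making the objective deterministic and monotone, so the
bisection converges despite Monte Carlo noise; the default amplitude
tolerance (2%) reflects that noise at the default photon count. The
signal at f = 20/mm originates within the top ~100 um, so these runs use
a shallow depth cutoff (default 0.25 mm keeps the estimate unbiased
while cutting the per-photon cost and the incoherent noise floor by an
order of magnitude). Recovery precision is set by the amplitude
signal-to-noise ratio and the shallow slope of \(|R(20)|\) in
\(\mu_s\) (about 0.6 in log-log); expect tens of percent at the default
2e5 photons per evaluation and ~5% at 1e7, tightening with the square
root of the photon count.

## The demodulation pipeline

Three reflectance images \(P_1, P_2, P_3\) are captured under projection
phases 0/120/240 degrees. The pipeline, in the fixed order
dark-subtraction, 8x8 software binning, Butterworth high-pass, three-phase
demodulation:

\[
DC = \tfrac13 (P_1 + P_2 + P_3), \qquad
AC = \tfrac{\sqrt2}{3}\sqrt{(P_1-P_2)^2 + (P_2-P_3)^2 + (P_3-P_1)^2},
\]

which recovers the local modulation amplitude exactly for an ideal
three-phase sinusoid, independent of the local pattern phase. The order
is pinned by tests because binning and filtering do not commute.

* **Dark referencing** subtracts per-phase images of the probe in a black
  water-filled container (internal reflections only), clipped at zero.
* **Binning** is a plain k x k block mean (k = 8), a dynamic-range step.
  It attenuates a sinusoid at frequency f by the Dirichlet factor
  \(\sin(\pi f k \Delta)/(k \sin(\pi f \Delta))\); tests correct for this
  known transfer when comparing recovered amplitudes with ground truth.
* **High-pass filtering** suppresses the slowly varying projection
  boundary artifact that arises when few pattern periods fit in the small
  field of view. The filter is a radially symmetric frequency-domain
  Butterworth high-pass with two poles and cutoff at one quarter of the
  projection frequency (gain \(1/\sqrt{1+(f_c/\rho)^{4}}\), DC removed
  exactly); the image is mean-filled outside the fiber mask and
  mirror-extended before the FFT to limit ringing. A radial 2-D filter is
  used because the boundary artifact is not axis-aligned.
* **ROI statistics** average over a central circle (default 600 um
  diameter, i.e. the central part of the 900 um field; a
  fraction-of-field alternative is available) to stay clear of residual
  boundary artifacts.
* **Reference normalisation** divides the tissue AC by that of an
  identically processed scattering-reference scan (an Intralipid
  emulsion in the modelled instrument), giving dimensionless reflectance
  factors and cancelling system transfer, including the binning
  attenuation.

## The synthetic generator

`make_phase_stack()` renders what the camera sees: an elliptical fiber
field (minor/major = cos 20 deg from the oblique polish), a large diffuse
DC background with a weak sinusoidal AC riding on it (default AC/DC =
10%, the epithelial fraction of the backscattering signal), a dark
offset for internal reflections, Gaussian read noise plus
signal-proportional shot-like noise, and 8-bit quantisation. Defaults:
900 um field, 2 um pixels, DC 180 counts, dark 8 counts, read noise 1.5
counts, shot scale 0.05 counts of variance per count of signal —
plausible for an 8-bit machine-vision camera behind a beam splitter. The
generator does **not** render the individual fiber cores of the bundle
(the 8x8 binning of the real pipeline erases them at analysis scale) nor
any lateral tissue heterogeneity; passing round-trip tests therefore
demonstrates pipeline correctness, not robustness to comb artifacts or
heterogeneous fields. Acetowhitening is representable only as a static
AC gain multiplier.

`make_study()` draws a multi-case cohort on the layout of the packaged
per-case scan-count table (13 cases; 19/5/47/5/10/16 scans in categories
BC/AIS/BS/CIN1/CIN2/CIN3; 102 in total). Per-category distributions of
the low-frequency reflectance `R3` and the backscattering ratio
`R9/R3` are lognormal — positive support and multiplicative spread match
the large ratio-scale variability seen between and especially within
patients — with a multiplicative per-case random effect. The default
medians encode the expected effect direction only (high-grade lesions:
ratio up, `R3` slightly down; columnar tissue darker): true per-category
distributions are not published, so the defaults are explicitly
qualitative, and classifier performance on synthetic cohorts is a check
of the bookkeeping, never a claim about clinical accuracy.

## Diagnostics

The depth-dependent diagnostic is the pixelwise backscattering ratio
\(R(9)/R(3)\), computed per pixel *before* ROI averaging (the two orders
differ on heterogeneous images; tests pin the pixelwise-first
convention). Case-wise normalisation divides each scan by its case's
mean benign-squamous value (reflectance mode: all four frequencies by
the case-mean BS `R3`; ratio mode: the ratio by the case-mean BS ratio),
which removes between-patient factors exactly and is idempotent. Group
summaries are five-number boxplot statistics with type-7 (linear
interpolation) quartiles — a convention the package pins because none is
canonical. `classify_linear()` scores a straight line in the
(`R3`, ratio) plane: positives above the line, sensitivity over
CIN2+CIN3, specificity over BS+CIN1, columnar categories excluded. The
line is configuration, not a fitted model: no claim is made of
reproducing any particular clinical sensitivity/specificity pair, which
would require the original patient images.

## Problem sizes and numerical conventions

The packaged studies use these sizes, chosen to keep a full run on one
CPU core in the tens of minutes while holding the Monte Carlo noise on
each reported quantity near or below its interpretation threshold:

* penetration-depth grid (\(\mu_s' \in \{1, 2\}\)/mm x
  \(\sigma \in \{1.0, 1.1, 1.2\}\), g = 0.9): per point, three
  replicates of 6e6 photons for the f = 3/mm study and three of 2e7
  (4e7 at \(\mu_s' = 2\), whose f = 15/mm amplitude sits closest to
  the incoherent noise floor) for the f = 15/mm study, summarised by
  replicate medians;
* single-condition depth-trend check: 1.5e7 photons;
* scattering-coefficient recovery: 1.2e7 photons per bisection
  evaluation at a 0.1 mm cutoff with a 0.3 mm detection window;
* demodulation identity: 1000 random draws, exact to 1e-9 relative.

Degenerate inputs are defined errors: empty detection sets warn (an
empty ROI or all-masked image stops), a zero reference or a zero
denominator pixel is masked or rejected, total internal reflection of
the illumination is rejected at construction, and frequencies beyond the
bin Nyquist limit are refused rather than aliased.

## Known limitations

* The medium is homogeneous and semi-infinite: no epithelium/stroma
  layering, so depth quantiles describe the homogeneous-medium signal
  origin, not a two-layer tissue.
* The acceptance cone is hard; the instrument's Gaussian-ish fiber
  acceptance would soften the exit-angle weighting.
* The phase-function second parameter (anisotropy) is a modelling choice
  (g = 0.9); penetration depths, especially d95 at low frequency and the
  f = 15/mm quantiles, shift by tens of percent across plausible g.
* The synthetic images are smooth and homogeneous; comb structure,
  speckle, registration drift and tissue heterogeneity are out of scope.
* Multi-wavelength evaluation and acetowhitening kinetics are carried as
  metadata/one multiplier only.
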