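---
title: "Simulating and detecting the t^(-1/2) signature of axon caliber variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting the t^(-1/2) signature of axon caliber variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonwalk)
```

## The model

Water diffusion inside an axon is effectively one-dimensional at clinical
diffusion times: the diffusion length (~10 µm) far exceeds the axon caliber
(~1 µm). Axons are not featureless tubes, though — their caliber varies
along the axis, with focal swellings (beads, varicosities) and
constrictions. Those caliber maxima act as restrictions to axial diffusion.
When the restrictions are placed with a finite correlation length
(*short-range disorder*, structural exponent $p = 0$), coarse-graining of
the 1-d medium by the growing diffusion length forces the time-dependent
axial diffusivity to approach its bulk limit as a power law

$$D(t) \simeq D_\infty + c\, t^{-\vartheta}, \qquad
  \vartheta = \tfrac{p + d}{2} = \tfrac12 \ (d = 1),$$

with the amplitude $c$ measuring the strength of the restrictions. The
structural side of the story lives in the 1-d power spectrum of the
cross-sectional area $A(z) = \pi r^2(z)$:

$$\Gamma_{1d}(k_z) = \frac{|A(k_z)|^2}{V\,\bar A},$$

whose low-$k$ plateau (units µm) both diagnoses short-range disorder and
is predicted by the restriction statistics,

$$\left.\Gamma_{1d}\right|_{k_z \to 0} \simeq
  \frac{\sigma_a^2}{\bar a^2}\cdot\frac{\bar l^2}{\bar a},$$

where $\bar a$ and $\sigma_a$ are the mean and SD of the spacing between
restrictions and $\bar l$ the mean restriction width. The package
implements the whole chain: substrate generation, morphometry,
Monte-Carlo diffusion, cumulants $D(t)$/$K(t)$, and power-law inference,
so the $t^{-1/2}$ signature can be produced and tested end to end without
any microscopy data.

## Synthetic substrates: what the generator emulates

`generate_restriction_positions()` places caliber maxima by a renewal
process with gamma-distributed spacings (positive support; the two moments
match the measured histogram: $\bar a = 5.70$ µm, $\sigma_a = 2.88$ µm).
A gamma family is the simplest positive renewal law with independently
tunable mean and SD; the defaults are the measured restriction statistics
of segmented corpus-callosum axons, and they are treated as study
conditions, not tuning knobs. `generate_radius_profile()` superimposes a
unit-height raised-cosine bump of FWHM $\bar l$ (default 5.6 µm) at each
position, scaled by the fractional `amplitude` (default 0.3) on a baseline
radius `r0` (default 0.5 µm, a typical inner radius of a myelinated
caliber-0.5–1.3 µm axon). Overlapping bumps add linearly in radius.

Three consequences of these modelling choices matter when interpreting
tests:

* **Effective restriction width.** The plateau formula above is written
  for the *area* fluctuation produced by restrictions of shape integral
  $\bar l$. Radius bumps of fractional amplitude $a$ enter the area to
  first order with weight $2a$, and the mean area is inflated by the mean
  bump coverage $a\bar l/\bar a$, so the generator's effective width is
  $l_{\rm eff} = 2a\bar l/(1 + a\bar l/\bar a)$. The spectral-consistency
  checks compare the measured plateau against the formula evaluated at
  $l_{\rm eff}$; agreement is within a few percent for amplitudes up to
  0.3, and within the 25% band used by the tests.
* **Merging of maxima.** Because $\bar l \simeq \bar a$ in the measured
  statistics, adjacent additive bumps merge, and the local-maxima detector
  then sees fewer, wider beads than were drawn (the positions of maxima of
  a sum of unit bumps do not depend on the overall amplitude, so no
  amplitude choice avoids this). Recovery of placement statistics by
  `find_restrictions()` is therefore validated on substrates with
  resolvable beads ($\bar l = 1.5$ µm); on real caliber profiles the
  detector plays the same role it plays on the microscopy-derived data,
  where maxima are genuinely distinct.
* **Amplitude is the only free parameter.** It is calibrated through the
  caliber coefficient of variation CV$(r)$ it induces (amplitude 0.3 gives
  CV$(r) \approx 0.14$ on the default geometry, in the observed range);
  all other generator defaults come directly from the measured statistics.

`make_scenario()` derives the four canonical geometries used to isolate
the cause of the time dependence: full geometry with mitochondria (I),
the same without compartment contrast (II), caliber variation only (III),
and undulation only (IV, a constant-section tube along the Gaussian-
smoothed, $\sigma_s = 1$ µm, skeleton whose radius is calibrated by
bisection so the voxelized volume matches the source volume to $10^{-3}$).

**Mitochondria.** Inclusions are z-aligned rods of radius $0.45\langle
r\rangle$ and length 1–2 µm, seeded with per-slice probability
$\propto A(z)^2$ until the target volume fraction (default 6%) is reached.
The quadratic weighting mirrors the observed quadratic relation between
local diameter and mitochondrial volume per unit length, and the rod
caliber reproduces the observed partition — a mitochondrion occupies
roughly a fifth of the local cross-section, so 6% by volume occupies
roughly a third of the axon length. (Thinner rods would need to cover
nearly the whole axon to reach 6%, erasing the caliber association the
geometry is supposed to carry.)

## The random walk

`run_walk()` advances walkers in continuous space with a fixed step
$\sqrt{6 D \delta t}$ in the current compartment and isotropic random
directions (Marsaglia sampling). The defaults tie the step to the voxel
size ($\text{step} = h/2$ with $h = 0.1$ µm, giving $\delta t \approx
2.1\times10^{-4}$ ms in axoplasm — essentially the reference step of
0.049 µm at $\delta t = 2\times10^{-4}$ ms). Boundary handling:

* **Exterior (cell membrane):** elastic specular reflection off the
  crossed voxel face(s); for a wall parallel to the axis this preserves
  the axial increment exactly, which keeps the axial diffusivity of a
  straight cylinder unbiased. At re-entrant corners where the reflected
  point is still exterior the walker waits one step; the residual bias is
  $O(\text{step}/r)$ and is covered by a step-refinement test.
* **Axoplasm–mitochondrion interface:** one-step transit accepted with
  $P_{1\to2} = \min(1, \sqrt{D_2/D_1})$, the standard rule for highly
  permeable membranes. With endpoint-based membrane detection this rule
  alone is not sufficient: a closed two-compartment box then equilibrates
  to walker density $\propto 1/\sqrt{D}$ instead of uniform (we verified
  this in a 1-d closed-form toy as well as in the 3-d kernel). The kernel
  therefore rescales the part of the accepted step beyond the crossed
  interface by the step-length ratio $\sqrt{D_2/D_1}$ of the two media;
  with the rescale the box equilibrates to occupancies proportional to
  compartment volumes (0.50 within Monte-Carlo error at $D_a/D_m =
  2/0.13$), which is the stated purpose of the rule.
* **z boundaries:** mirrored reflective copies of the substrate; the true
  displacement accumulates in the unfolded coordinate, so the finite
  length never truncates a path. Mirror planes coincide with voxel
  boundaries, which lets face reflection work directly in unfolded
  coordinates.
* **T2 weighting (scenario I):** each walker carries
  $w = \exp(-\sum \delta t / T_2(\text{label}))$, accumulated along its
  trajectory up to the sampling time and applied to the displacement
  moments. This is one consistent reading of weighting by transverse
  relaxation; a uniform $T_2$ cancels exactly, which is tested.

RNG streams are per-walker (xoshiro256+ seeded by splitmix64 from the
(seed, walker) pair), so results are bitwise reproducible and independent
of execution order.

## From moments to the power law

Weighted second and fourth displacement moment tensors are recorded at
each sampled time; `apparent_D()` and `apparent_K()` contract them along
any direction ($D = \langle s^2\rangle/2t$,
$K = \langle s^4\rangle/\langle s^2\rangle^2 - 3$). Orientation dispersion
is applied analytically: a direction $\hat n'$ drawn from the Watson
distribution contributes along the bundle axis through its mirror image
$\hat n = 2(\hat n'\cdot\hat z)\hat z - \hat n'$, so one simulation per
axon serves every dispersion level. Ensemble averaging is volume-weighted
(`ensemble_D()`, `ensemble_K()`, with the inter-/intra-axonal kurtosis
split reported separately), signals follow the cumulant expansion
truncated at $b^2$, and `fit_dki_wlls()` inverts them by weighted linear
least squares with weights $S^2$ — the standard weighting that undoes the
noise amplification of the log transform.

`fit_power_law()` regresses $D(t)$ on $1/\sqrt t$ over a window of
20–80 ms. The exponent is fixed at 1/2 (a free-exponent fit exists as a
diagnostic only); the window starts late enough for coarse-graining to be
established ($t \gg \bar a^2/2D_\infty \approx 9$ ms) and ends where the
finite substrate length would otherwise bound the diffusion length. The
one-sided p-value of the slope tests the null of no positive
$1/\sqrt t$ correlation. For strongly dispersed bundles
`fit_power_law_corrected()` adds a $c'/t$ regressor absorbing the
transverse (radially restricted, $\propto 1/t$) contribution that leaks
into the axial projection.

**Conditioning caveat.** Over a 20–80 ms window $1/\sqrt t$ and $1/t$ are
nearly collinear; at Monte-Carlo noise levels the three-parameter fit is
ill-conditioned (we measured errors on $c$ an order of magnitude larger
than the $\approx +0.02$ bias the correction removes). The corrected fit
is therefore demonstrated on the noise-free projected ensemble — the
axial power law fitted to the simulation plus its measured transverse
saturation, projected exactly over Watson draws — where it restores the
$\langle\cos^2\theta\rangle$ scaling that the uncorrected fit misses. On
measured data the correction should only be trusted with a long,
well-sampled time range.

## Problem sizes and numerical choices

The bundled tests and checks run at desk scale, chosen so the whole suite
completes in minutes while every quantitative claim keeps a quantified
error bar: single axons of 60–150 µm (10–26 beads), voxel size 0.1 µm,
$2\,000$–$30\,000$ walkers per substrate, and times up to 80–100 ms.
Monte-Carlo uncertainties are handled by replicate seeds (with
analytic-floor standard errors for free diffusion, so an unluckily small
sample SD cannot tighten a test) or by the OLS covariance of the final
fit. Degenerate inputs are first-class: zero spacing SD gives periodic
beads, amplitude zero a cylinder, $\kappa = \infty$ a perfectly aligned
bundle, and exact (zero-residual) fits report $p = 1/2$ for a zero slope
rather than a 0/0 artifact. Plateau-equal maxima are resolved leftmost;
spectra are rectangular-window periodograms with the mean subtracted
before transforming, since the spectral leakage of the mean would
otherwise bury the low-$k$ plateau of a finite profile.

## What passing tests do and do not show

The generator emulates the *statistics* the theory cares about — renewal
placement, bead width, caliber CV, mitochondria–caliber association,
undulation, Watson dispersion — not the full morphology of real axons
(non-circular cross-sections, spines, myelin, extra-axonal space are all
absent). Passing the acceptance properties shows that the implementation
reproduces the predicted structure–dynamics links on substrates whose
ground truth is known exactly; it does not by itself validate the model
on tissue. The quantitative outputs on real data would additionally
depend on segmentation quality and on the extra-axonal compartment, which
is out of scope here.

## Session info

```{r}
sessionInfo()
```
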