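# axonwalk

Monte-Carlo diffusion simulation and time-dependence analysis in beaded
axon substrates.

## The problem

Diffusion MRI measures water displacement at millimetre resolution, yet
the biology it should report on — axon beading, caliber variation,
mitochondria — lives at the micrometre scale. One bridge across that gap
is the *time dependence* of the axial diffusion coefficient inside axons.
If the restrictions to diffusion along an axon (local caliber maxima,
i.e. beads or varicosities) are placed with short-range disorder
(structural exponent p = 0), coarse-graining predicts a signature power
law for the along-fiber diffusivity,

    D(t) ≈ D∞ + c · t^(−1/2),

with bulk diffusivity D∞ and restriction strength c. The structural
counterpart is the one-dimensional power spectrum of the cross-sectional
area A(z) = π r²(z): short-range disorder shows up as a low-k plateau
whose level is set by the restriction statistics,

    Γ_1d(k→0) ≈ (σ_a²/ā²) · (l̄²/ā),

where ā and σ_a are the mean and SD of the spacing between restrictions
and l̄ the mean restriction width.

`axonwalk` implements the full chain for anyone who wants to generate,
simulate and analyse this physics without microscopy data: synthetic 3-D
intra-axonal substrates (beading, undulation, mitochondria, Watson
orientation dispersion), a compiled continuous-space random-walk kernel
with membrane permeation and T2 weighting, displacement-moment cumulants
D(t) and K(t) along arbitrary directions, dMRI signal synthesis with
weighted linear least-squares kurtosis fitting, structural power spectra,
and the power-law and rank statistics used to detect the t^(−1/2)
signature. Everything is tibble-first and pipe-friendly, with
`tidy()`/`glance()`/`autoplot()` methods on the fitted objects.

## Worked example

Structure first: generate beaded axons at the measured restriction
statistics (spacing 5.70 ± 2.88 µm, width 5.6 µm), and compare the
measured spectral plateau with the closed-form prediction:

```r
library(axonwalk)
spec <- bead_spec()   # a = 5.70 um (SD 2.88), l = 5.6 um, amplitude 0.3

plateaus <- vapply(1:20, function(s) {
  pos  <- generate_restriction_positions(400, spec, seed = s)
  prof <- generate_radius_profile(pos, spec, dz = 0.1)
  estimate_plateau_and_p(power_spectrum_density(prof),
                         a_mean = spec$a_mean)$plateau
}, numeric(1))

mean(plateaus) / spec$a_mean                       # measured Gamma/a
#> [1] 0.05252022
l_eff <- 2 * spec$amplitude * spec$l_mean /
  (1 + spec$amplitude * spec$l_mean / spec$a_mean)
plateau_short_range(spec$a_mean, spec$a_sd, l_eff) # predicted Gamma/a
#> [1] 0.05291772
```

The measured low-k plateau of the caliber power spectrum agrees with the
short-range-disorder prediction to within 1% (the prediction uses the
generator's effective restriction width `l_eff`; see the methods
vignette). The reference closed forms evaluated at the measured axon
statistics:

```r
plateau_short_range(5.70, 2.88, 5.6)   # normalized plateau
#> [1] 0.2464119
width_from_plateau(0.25, 5.70, 2.88)   # restriction width from a plateau
#> [1] 5.640625
kappa_to_theta(c(Inf, 15.4, 4.7, 1.65))# Watson dispersion angles (deg)
#> [1]  0.00000 15.06010 30.11567 45.24640
```

Dynamics second: walk 30 000 water molecules through a 150-µm beaded
axon (caliber variation only) and fit the power law over 20–80 ms. This
is the expensive step (a few minutes on one CPU):

```r
pos  <- generate_restriction_positions(150, spec, seed = 11)
prof <- generate_radius_profile(pos, spec, dz = 0.1)
vol  <- make_scenario(prof, "III", h = 0.1)   # axially symmetric tube
cfg  <- sim_config(n_walkers = 30000,
                   sample_times = c(1, 2, 3, 5, 8, 12, seq(20, 80, 6)),
                   seed = 77)
rec  <- run_walk(vol, compartment_props(), cfg)
fit_power_law(apparent_D(rec, c(0, 0, 1)), window = c(20, 80))
#> <powerlaw_fit> D(t) = D_inf + c/sqrt(t), window 20-80 ms
#>   D_inf = 1.767 (SE 0.013) um^2/ms
#>   c     = 0.4931 (SE 0.083) um^2 ms^-1/2
#>   one-sided p (positive slope) = 0.000168, n = 10
```

The axial diffusivity is depressed below the intrinsic 2 µm²/ms and
approaches its bulk value as 1/√t with a significantly positive
amplitude c — the caliber-variation signature. A straight cylinder of the
same volume shows c consistent with zero, and an undulation-only
substrate nearly so; orientation dispersion scales both D∞ and c by
⟨cos²θ⟩ (see `sample_watson()`, `reflect_direction()`,
`dispersion_scaling()`, and the acceptance tests).

A command-line driver for the whole pipeline lives in `inst/cli/axonwalk`
(subcommands `generate-substrate`, `morphometry`, `simulate`, `fit-dt`,
`run-all`).

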