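test_that("cross-section series reads geometry back from masks", {
  cs <- cross_section_series(cylinder_volume(r = 1, L = 5, h = 0.1))
  expect_true(all(abs(cs$area - pi) / pi < 0.02))
  expect_lt(sd(cs$cx), 1e-9)

  prof <- beaded_profile(3, L = 25)
  cs3 <- cross_section_series(make_scenario(prof, "III", h = 0.1))
  r_src <- stats::approx(prof$z, prof$r, xout = cs3$z, rule = 2)$y
  expect_lt(max(abs(cs3$r_eq - r_src)), 3 * 0.1)  # O(h)

  skel <- generate_skeleton(25, amplitude = 0.5, wavelength = 12, dz = 0.1,
                            seed = 9)
  v4 <- make_scenario(prof, "IV", skeleton = skel, h = 0.1)
  cs4 <- cross_section_series(v4)
  expect_lt(sd(cs4$area) / mean(cs4$area), 0.05)
  # centroid track follows the (smoothed) skeleton shape
  sk_s <- axonwalk:::gaussian_smooth(skel$x, 1, 0.1)
  x_ref <- stats::approx(skel$z, sk_s - mean(sk_s), xout = cs4$z, rule = 2)$y
  expect_gt(cor(cs4$cx - mean(cs4$cx), x_ref), 0.95)
})

test_that("concatenation is a seeded permutation preserving total length", {
  p1 <- radius_profile(rep(1, 50), 0.1)
  expect_equal(concatenate_profiles(list(p1), seed = 1)$r, p1$r)
  profs <- normalize_volumes(lapply(1:5, beaded_profile, L = 20))
  c1 <- concatenate_profiles(profs, seed = 4)
  c2 <- concatenate_profiles(profs, seed = 4)
  expect_identical(c1$r, c2$r)
  expect_equal(profile_length(c1),
               sum(vapply(profs, profile_length, numeric(1))))
  # 227 axons of ~18 um concatenate to ~4 mm
  many <- lapply(1:227, function(i) radius_profile(rep(0.5, 180), 0.1))
  expect_equal(profile_length(concatenate_profiles(many, seed = 1)),
               227 * 18)
})

test_that("caliber power spectrum matches a direct DFT and known limits", {
  # constant profile: no fluctuations at any k > 0
  ps0 <- power_spectrum_density(radius_profile(rep(1, 256), 0.1))
  expect_lt(max(ps0$gamma), 1e-20)

  # brute-force DFT oracle on an arbitrary profile
  prof <- beaded_profile(5, L = 30)
  ps <- power_spectrum_density(prof)
  A <- pi * prof$r^2
  dz <- 0.1
  v <- sum(A) * dz
  direct <- vapply(ps$k[1:8], function(kk) {
    Mod(sum((A - mean(A)) * exp(-1i * kk * prof$z)))^2 * dz^2 /
      (v * mean(A))
  }, numeric(1))
  expect_equal(ps$gamma[1:8], direct, tolerance = 1e-8)

  # periodic beads: suppressed low-k plateau, Bragg peak at k = 2 pi / a.
  # Beads narrower than the spacing, so the bump form factor does not kill
  # the first Bragg order.
  per <- bead_spec(a_sd = 0, l_mean = 2)
  prof_p <- generate_radius_profile(
    generate_restriction_positions(399.1, per, seed = 1), per, dz = 0.1
  )
  ps_p <- power_spectrum_density(prof_p)
  low <- estimate_plateau_and_p(ps_p, a_mean = per$a_mean)$plateau
  k_peak <- ps_p$k[which.max(ps_p$gamma)]
  expect_lt(low, 0.02 * max(ps_p$gamma))
  expect_lt(abs(k_peak - 2 * pi / per$a_mean), 0.02)
})

test_that("low-k plateau of generated substrates matches the closed form", {
  # the plateau prediction takes the generator's effective restriction
  # width: 2 a l / (1 + a l / abar) for fractional radius bumps of
  # amplitude a (the area fluctuation is 2a * bump, and the mean area is
  # inflated by the mean bump coverage)
  spec <- bead_spec(amplitude = 0.3)
  pl <- vapply(1:50, function(s) {
    prof <- beaded_profile(s, L = 400, spec = spec)
    estimate_plateau_and_p(power_spectrum_density(prof),
                           a_mean = spec$a_mean)$plateau
  }, numeric(1))
  l_eff <- 2 * spec$amplitude * spec$l_mean /
    (1 + spec$amplitude * spec$l_mean / spec$a_mean)
  pred <- plateau_short_range(spec$a_mean, spec$a_sd, l_eff) * spec$a_mean
  expect_lt(abs(mean(pl) / pred - 1), 0.25)
})

test_that("position spectra separate periodic, renewal and Poisson order", {
  per <- generate_restriction_positions(1999.5, bead_spec(a_sd = 0), seed = 1)
  pl_per <- estimate_plateau_and_p(position_spectrum(per),
                                   a_mean = 5.7)$plateau
  expect_lt(pl_per, 0.02)

  pl_gam <- mean(vapply(1:50, function(s) {
    pos <- generate_restriction_positions(2000, bead_spec(), seed = s)
    estimate_plateau_and_p(position_spectrum(pos), a_mean = 5.7)$plateau
  }, numeric(1)))
  expect_lt(abs(pl_gam - (2.88 / 5.70)^2), 0.1 * (2.88 / 5.70)^2)

  pl_poi <- mean(vapply(1:30, function(s) {
    pos <- generate_restriction_positions(
      3000, bead_spec(a_mean = 5, a_sd = 5), seed = s
    )
    estimate_plateau_and_p(position_spectrum(pos), a_mean = 5)$plateau
  }, numeric(1)))
  expect_lt(abs(pl_poi - 1), 0.1)
  # monotone ordering: periodic < renewal < Poisson
  expect_true(pl_per < pl_gam && pl_gam < pl_poi)
  expect_error(position_spectrum(1:5), class = "axonwalk_error")
})

test_that("plateau and structural exponent estimation behave on synthetic spectra", {
  k <- seq(0.02, 0.4, by = 0.02)
  flat <- axonwalk:::new_power_spectrum(k, rep(2, length(k)), 1, "of-density")
  est <- estimate_plateau_and_p(flat, k_max = 0.4)
  expect_equal(est$plateau, 2)
  expect_lt(abs(est$p), 1e-10)
  expect_true(est$short_range)

  quad <- axonwalk:::new_power_spectrum(k, k^2, 1, "of-density")
  est2 <- estimate_plateau_and_p(quad, k_max = 0.4)
  expect_equal(est2$p, 2, tolerance = 1e-10)
  expect_false(est2$short_range)

  # beaded substrates look short-range disordered
  p_est <- vapply(1:20, function(s) {
    prof <- beaded_profile(s, L = 400)
    estimate_plateau_and_p(power_spectrum_density(prof), a_mean = 5.7)$p
  }, numeric(1))
  expect_lt(abs(mean(p_est)), 0.3)
  expect_error(estimate_plateau_and_p(flat, k_max = 0.05),
               class = "axonwalk_error")
})

test_that("plateau closed form and its inverse reproduce the printed values", {
  expect_equal(round(plateau_short_range(5.70, 2.88, 5.6), 2), 0.25)
  expect_equal(plateau_short_range(5.70, 0, 5.6), 0)
  expect_equal(round(width_from_plateau(0.25, 5.70, 2.88), 1), 5.6)
  expect_error(width_from_plateau(0.25, 5.70, 0), class = "axonwalk_error")
  # round trip at arbitrary arguments
  pl <- plateau_short_range(4.2, 1.7, 3.3)
  expect_equal(width_from_plateau(pl, 4.2, 1.7), 3.3, tolerance = 1e-12)
})

test_that("restriction detection recovers placement statistics", {
  # pure sinusoid: spacings exactly one period
  z <- (1:4000 - 0.5) * 0.1
  sine <- radius_profile(1 + 0.2 * sin(2 * pi * z / 5), 0.1)
  rs <- find_restrictions(sine)
  expect_equal(diff(rs$positions), rep(5, rs$n - 1L), tolerance = 1e-9)
  expect_lt(rs$a_sd, 1e-9)

  # generator output with resolvable beads: statistics recovered
  spec <- bead_spec(l_mean = 1.5)
  rec <- vapply(1:40, function(s) {
    rs <- find_restrictions(beaded_profile(s, L = 400, spec = spec))
    c(rs$a_mean, rs$a_sd)
  }, numeric(2))
  expect_lt(abs(mean(rec[1, ]) - 5.70) / 5.70, 0.05)
  expect_lt(abs(mean(rec[2, ]) - 2.88) / 2.88, 0.15)

  expect_error(find_restrictions(radius_profile(rep(1, 100), 0.1)),
               class = "axonwalk_error_no_maxima")
})
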