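test_that("directional diffusivity contracts the moment tensor correctly", {
  t <- c(1, 2)
  rec <- gaussian_record(t, vx = 2 * t, vy = 2 * t, vz = 4 * t)
  expect_equal(apparent_D(rec, c(0, 0, 1))$D, c(2, 2))
  expect_equal(apparent_D(rec, c(1, 0, 0))$D, c(1, 1))
  n45 <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_equal(apparent_D(rec, n45)$D, c(1.5, 1.5))
  # isotropic record: same D along any direction
  iso <- gaussian_record(t, 2 * t, 2 * t, 2 * t)
  set.seed(1)
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
  expect_equal(apparent_D(iso, v)$D, c(1, 1), tolerance = 1e-12)
  expect_error(apparent_D(rec, c(1, 1, 0)),
               class = "axonwalk_error_invalid_direction")
  expect_error(apparent_D(rec, c(0, 0, 1), t = 5),
               class = "axonwalk_error_time_not_sampled")
})

test_that("directional kurtosis reproduces closed-form non-Gaussian cases", {
  t <- c(1, 3)
  # Gaussian: K = 0 along any axis
  g <- gaussian_record(t, 2 * t, 2 * t, 2 * t)
  expect_equal(apparent_K(g, c(0, 0, 1))$K, c(0, 0), tolerance = 1e-12)
  # equal mixture of 1d Gaussians with variances {2t, 4t}: K = 1/3
  mix <- axial_record(t, m2_zz = 3 * t, m4_zzzz = 0.5 * (3 * (2 * t)^2 +
                                                           3 * (4 * t)^2))
  expect_equal(apparent_K(mix, c(0, 0, 1))$K, c(1 / 3, 1 / 3),
               tolerance = 1e-12)
  # symmetric two-point displacement +-a: K = -2
  two <- axial_record(t, m2_zz = rep(4, 2), m4_zzzz = rep(16, 2))
  expect_equal(apparent_K(two, c(0, 0, 1))$K, c(-2, -2), tolerance = 1e-12)
})

test_that("direction reflection about the z axis", {
  expect_equal(reflect_direction(c(0, 0, 1)), c(0, 0, 1))
  expect_equal(reflect_direction(c(1, 0, 0)), c(-1, 0, 0))
  s <- sin(pi / 4)
  expect_equal(reflect_direction(c(s, 0, s)), c(-s, 0, s))
  # z component always preserved, norm preserved
  set.seed(2)
  M <- matrix(stats::rnorm(30), 10, 3)
  M <- M / sqrt(rowSums(M^2))
  R <- reflect_direction(M)
  expect_equal(R[, 3], M[, 3])
  expect_equal(rowSums(R^2), rep(1, 10))
  expect_error(reflect_direction(c(1, 1, 1)),
               class = "axonwalk_error_invalid_direction")
})

make_ensemble <- function(n_axons, t, seed) {
  set.seed(seed)
  f <- stats::runif(n_axons); f <- f / sum(f)
  dplyr::bind_rows(lapply(seq_len(n_axons), function(i) {
    tibble::tibble(axon = i, f = f[i], t = t,
                   D = stats::runif(length(t), 0.8, 2.2),
                   K = stats::runif(length(t), 0, 0.8))
  }))
}

test_that("ensemble cumulants match hand-computed mixtures", {
  t <- c(10, 20)
  ax <- dplyr::bind_rows(
    tibble::tibble(axon = 1, f = 0.5, t = t, D = 1, K = 0),
    tibble::tibble(axon = 2, f = 0.5, t = t, D = 2, K = 0)
  )
  expect_equal(ensemble_D(ax)$D, c(1.5, 1.5))
  ek <- ensemble_K(ax)
  expect_equal(ek$K, c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(ek$K_intra, c(0, 0))
  # identical Gaussian compartments: K = 0
  same <- dplyr::mutate(ax, D = 1.5)
  expect_equal(ensemble_K(same)$K, c(0, 0))
  # single axon: identity
  one <- tibble::tibble(axon = 1, f = 1, t = t, D = 1.3, K = 0.2)
  expect_equal(ensemble_D(one)$D, c(1.3, 1.3))
  expect_equal(ensemble_K(one)$K, c(0.2, 0.2))
  bad <- dplyr::mutate(ax, f = 0.4)
  expect_error(ensemble_D(bad), class = "axonwalk_error_fractions")
  # nonnegative per-axon kurtosis gives nonnegative ensemble kurtosis
  for (s in 1:5) {
    expect_true(all(ensemble_K(make_ensemble(6, t, s))$K >= 0))
  }
})

test_that("ensemble formulas equal the small-b Taylor coefficients of the signal", {
  t <- c(20, 50)
  ax <- make_ensemble(10, t, seed = 3)
  b <- seq(0.002, 0.010, by = 0.002)
  sig <- synthesize_signal(ax, b)
  for (tt in t) {
    y <- -log(sig$signal[sig$t == tt])
    # exact degree-5 polynomial interpolation through b -> -log S
    cf <- solve(outer(b, 1:5, `^`), y)
    D_ref <- ensemble_D(ax); K_ref <- ensemble_K(ax)
    D_t <- D_ref$D[D_ref$t == tt]
    K_t <- K_ref$K[K_ref$t == tt]
    expect_equal(cf[1], D_t, tolerance = 1e-6)
    expect_equal(-6 * cf[2] / D_t^2, K_t, tolerance = 1e-5)
  }
})

test_that("signal synthesis matches closed forms and warns out of validity", {
  t <- 10
  ax <- dplyr::bind_rows(
    tibble::tibble(axon = 1, f = 0.5, t = t, D = 1, K = 0),
    tibble::tibble(axon = 2, f = 0.5, t = t, D = 2, K = 0)
  )
  sig <- synthesize_signal(ax, c(0, 1))
  expect_equal(sig$signal[sig$b == 0], 1)
  expect_equal(sig$signal[sig$b == 1], 0.5 * exp(-1) + 0.5 * exp(-2),
               tolerance = 1e-12)
  expect_equal(round(sig$signal[sig$b == 1], 4), 0.2516)
  one <- tibble::tibble(axon = 1, f = 1, t = t, D = 1.7, K = 0)
  s1 <- synthesize_signal(one, c(0, 0.5, 1.5))
  expect_equal(log(s1$signal), -s1$b * 1.7, tolerance = 1e-12)
  hot <- tibble::tibble(axon = 1, f = 1, t = t, D = 2, K = 3)
  expect_warning(synthesize_signal(hot, c(0, 1)), "validity")
})

test_that("weighted least-squares kurtosis fit recovers the generators", {
  t <- c(20, 40)
  # single Gaussian: D exact, K = 0 to numerical precision
  one <- tibble::tibble(axon = 1, f = 1, t = rep(t, each = 1), D = 1.5, K = 0)
  fit1 <- fit_dki_wlls(synthesize_signal(one, c(0, 0.4, 1, 1.5)))
  expect_equal(fit1$D, rep(1.5, 2), tolerance = 1e-10)
  expect_lt(max(abs(fit1$K)), 1e-10)
  # 10-axon ensemble with modest per-axon spread at the acquisition
  # b-values: close to the ensemble cumulants (the difference is the
  # truncation of the log-signal at O(b^2), which grows with the spread)
  set.seed(9)
  f <- stats::runif(10); f <- f / sum(f)
  ax <- dplyr::bind_rows(lapply(1:10, function(i) {
    tibble::tibble(axon = i, f = f[i], t = t,
                   D = stats::runif(length(t), 1.45, 1.85),
                   K = stats::runif(length(t), 0.1, 0.35))
  }))
  fit <- fit_dki_wlls(synthesize_signal(ax, c(0, 0.4, 1, 1.5)))
  ref <- dplyr::left_join(ensemble_D(ax), ensemble_K(ax), by = "t")
  expect_lt(max(abs(fit$D - ref$D) / ref$D), 0.02)
  expect_lt(max(abs(fit$K - ref$K) / ref$K), 0.05)
  expect_error(
    fit_dki_wlls(synthesize_signal(ax, c(0, 1))),
    class = "axonwalk_error_invalid_spec"
  )
})

test_that("projecting one axon over Watson draws recovers the cos^2 scaling", {
  t <- c(20, 40, 80)
  # near-1d stick: axial Gaussian, negligible transverse spread
  stick <- gaussian_record(t, vx = 1e-9 * t, vy = 1e-9 * t, vz = 2 * 2 * t)
  D0 <- apparent_D(stick, c(0, 0, 1))$D
  for (kap in c(15.4, 1.65)) {
    os <- sample_watson(kap, 4000, seed = 31)
    dirs <- reflect_direction(as.matrix(os))
    ax <- dplyr::bind_rows(lapply(seq_len(nrow(dirs)), function(i) {
      axon_cumulants(stick, dirs[i, ], f = 1 / nrow(dirs), id = i)
    }))
    ratio <- ensemble_D(ax)$D / D0
    cos2 <- os$z^2
    se <- sd(cos2) / sqrt(length(cos2))
    expect_lt(max(abs(ratio - watson_cos2(kap))), 3 * se)
  }
})
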