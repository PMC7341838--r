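# Small substrate fixtures built in code; everything deterministic by seed.

beaded_profile <- function(seed, L = 60, spec = bead_spec(), dz = 0.1) {
  pos <- generate_restriction_positions(L, spec, seed = seed)
  generate_radius_profile(pos, spec, dz = dz)
}

cylinder_volume <- function(r = 0.5, L = 40, h = 0.1) {
  voxelize(radius_profile(rep(r, round(L / 0.1)), 0.1), h = h)
}

# Analytic moment records for exercising the cumulant algebra without MC:
# Gaussian displacements with per-axis variances vx, vy, vz at times t.
gaussian_record <- function(t, vx, vy, vz) {
  n <- length(t)
  rec <- tibble::tibble(
    t = t, n_walkers = 1e6, weight_sum = 1e6,
    occ_axoplasm = 1e6, occ_mito = 0,
    m2_xx = vx, m2_xy = 0, m2_xz = 0, m2_yy = vy, m2_yz = 0, m2_zz = vz,
    m4_xxxx = 3 * vx^2, m4_xxxy = 0, m4_xxxz = 0, m4_xxyy = vx * vy,
    m4_xxyz = 0, m4_xxzz = vx * vz, m4_xyyy = 0, m4_xyyz = 0, m4_xyzz = 0,
    m4_xzzz = 0, m4_yyyy = 3 * vy^2, m4_yyyz = 0, m4_yyzz = vy * vz,
    m4_yzzz = 0, m4_zzzz = 3 * vz^2
  )
  structure(rec, dt = NA_real_, config = NULL,
            class = c("moment_record", class(rec)))
}

# Record with prescribed raw axial moments (m2_zz, m4_zzzz), transverse zero.
axial_record <- function(t, m2_zz, m4_zzzz) {
  eps <- 1e-12
  rec <- gaussian_record(t, eps, eps, m2_zz)
  rec$m4_zzzz <- m4_zzzz
  rec
}

# Exact one-sided signed-rank p-value by enumerating all 2^n sign vectors.
wilcoxon_enumerate <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% rk
  mean(w_all >= w_obs)
}

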