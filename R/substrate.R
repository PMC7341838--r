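#' Bead (caliber-restriction) specification
#'
#' Parameters of the stochastic beading model for a single axon: local
#' caliber maxima ("beads" or varicosities) are dropped along the axis with
#' gamma-distributed spacings and a smooth unimodal radius bump of
#' characteristic width `l_mean` at each one.
#'
#' Defaults are the restriction statistics measured on segmented corpus
#' callosum axons: mean spacing 5.70 um between local caliber maxima with
#' SD 2.88 um, and mean restriction width 5.6 um.
#'
#' @param a_mean Mean spacing between restrictions (um).
#' @param a_sd SD of the spacing (um); 0 gives exactly periodic beads.
#' @param l_mean Characteristic (FWHM) width of one bead (um).
#' @param amplitude Fractional radius modulation at an isolated bead peak.
#' @param r0 Baseline axon radius (um).
#' @return An object of class `bead_spec`.
#' @examples
#' bead_spec()
#' bead_spec(a_sd = 0, amplitude = 0.2)
#' @export
bead_spec <- function(a_mean = 5.70, a_sd = 2.88, l_mean = 5.6,
                      amplitude = 0.3, r0 = 0.5) {
  check_number(a_mean, "a_mean", lower = 1e-12)
  check_number(a_sd, "a_sd", lower = 0)
  check_number(l_mean, "l_mean", lower = 1e-12)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(r0, "r0", lower = 1e-12)
  structure(
    list(a_mean = a_mean, a_sd = a_sd, l_mean = l_mean,
         amplitude = amplitude, r0 = r0),
    class = "bead_spec"
  )
}

#' @export
print.bead_spec <- function(x, ...) {
  cat("<bead_spec>",
      sprintf(" spacing   a: %.3g um (SD %.3g um)", x$a_mean, x$a_sd),
      sprintf(" width     l: %.3g um", x$l_mean),
      sprintf(" amplitude  : %.3g", x$amplitude),
      sprintf(" base radius: %.3g um", x$r0),
      sep = "\n")
  invisible(x)
}

#' Compartment properties of the substrate
#'
#' Intrinsic diffusivities and transverse relaxation times of axoplasm
#' (label 1) and mitochondria (label 2), plus the target mitochondrial
#' volume fraction. Defaults follow the values used for the realistic
#' intra-axonal simulations: D_a = 2, D_m = 0.13 um^2/ms, T2_a = 80,
#' T2_m = 20 ms, f_m = 6%.
#'
#' @param D_a,D_m Intrinsic diffusivities (um^2/ms).
#' @param T2_a,T2_m Transverse relaxation times (ms).
#' @param f_m Target mitochondrial volume fraction in `[0, 0.5)`.
#' @return An object of class `compartment_props`.
#' @export
compartment_props <- function(D_a = 2, D_m = 0.13, T2_a = 80, T2_m = 20,
                              f_m = 0.06) {
  check_number(D_a, "D_a", lower = 0)
  check_number(D_m, "D_m", lower = 0)
  check_number(T2_a, "T2_a", lower = 1e-12)
  check_number(T2_m, "T2_m", lower = 1e-12)
  if (!is.numeric(f_m) || length(f_m) != 1L || is.na(f_m) ||
      f_m < 0 || f_m >= 0.5) {
    stop_axonwalk("`f_m` must lie in [0, 0.5).",
                  "axonwalk_error_invalid_spec")
  }
  structure(
    list(D_a = D_a, D_m = D_m, T2_a = T2_a, T2_m = T2_m, f_m = f_m),
    class = "compartment_props"
  )
}

#' Radius profile of one axon
#'
#' A discretized caliber function r(z) on a uniform grid. Stored as a tibble
#' with columns `z` (cell-centre coordinate, um) and `r` (radius, um); the
#' grid spacing is kept in the `dz` attribute and the total length is
#' `dz * nrow`.
#'
#' @param r Radii at successive grid points (um), all positive and finite.
#' @param dz Grid spacing (um).
#' @return A tibble of class `radius_profile` with columns `z`, `r`.
#' @export
radius_profile <- function(r, dz) {
  check_number(dz, "dz", lower = 1e-12)
  if (length(r) < 1L || !all(is.finite(r)) || !all(r > 0)) {
    stop_axonwalk("radii must be positive and finite",
                  "axonwalk_error_invalid_profile")
  }
  out <- tibble(z = (seq_along(r) - 0.5) * dz, r = as.numeric(r))
  structure(out, dz = dz, class = c("radius_profile", class(out)))
}

profile_dz <- function(profile) attr(profile, "dz", exact = TRUE)

#' @rdname radius_profile
#' @param profile A `radius_profile`.
#' @export
profile_length <- function(profile) nrow(profile) * profile_dz(profile)

#' Axon volume from a radius profile
#'
#' V = sum pi r(z)^2 dz, the volume of the axially symmetric body of
#' revolution described by the profile.
#'
#' @inheritParams profile_length
#' @return Volume (um^3).
#' @export
profile_volume <- function(profile) {
  sum(pi * profile$r^2) * profile_dz(profile)
}

#' Draw restriction (bead) positions along an axon
#'
#' Places local caliber maxima on `[0, L)` with independent successive
#' spacings drawn from a gamma distribution of mean `a_mean` and SD `a_sd`
#' (a renewal process: short-range disorder with a finite correlation
#' length). `a_sd = 0` degenerates to exactly periodic placement.
#'
#' @param L Axon length (um); must exceed `spec$a_mean`.
#' @param spec A [bead_spec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Increasing numeric vector of positions in `[0, L)`, with `L`
#'   attached as the `"L"` attribute.
#' @examples
#' generate_restriction_positions(100, bead_spec(), seed = 1)
#' @export
generate_restriction_positions <- function(L, spec, seed) {
  stopifnot(inherits(spec, "bead_spec"))
  check_number(L, "L", lower = 1e-12)
  if (L <= spec$a_mean) {
    stop_axonwalk(
      sprintf("substrate too short: L = %g um but mean spacing is %g um",
              L, spec$a_mean),
      "axonwalk_error_substrate_too_short"
    )
  }
  positions <- local_seed(seed, {
    n_max <- ceiling(3 * L / spec$a_mean) + 20L
    gaps <- draw_spacings(n_max, spec$a_mean, spec$a_sd)
    first <- stats::runif(1, 0, spec$a_mean)
    pos <- first + cumsum(c(0, gaps))
    while (max(pos) < L) {
      pos <- c(pos, max(pos) + cumsum(draw_spacings(n_max, spec$a_mean,
                                                    spec$a_sd)))
    }
    pos[pos < L]
  })
  structure(positions, L = L)
}

draw_spacings <- function(n, a_mean, a_sd) {
  if (a_sd == 0) return(rep(a_mean, n))
  shape <- (a_mean / a_sd)^2
  if (!is.finite(shape) || shape <= 0) {
    stop_axonwalk("spacing distribution has non-positive shape",
                  "axonwalk_error_invalid_spec")
  }
  stats::rgamma(n, shape = shape, scale = a_sd^2 / a_mean)
}

# Unit-height raised-cosine bump with FWHM 1, truncated at |u| = 1.
bead_bump <- function(u) {
  ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
}

#' Build a beaded radius profile from restriction positions
#'
#' Evaluates r(z) = r0 (1 + amplitude * sum_k g((z - z_k) / l_mean)) on a
#' uniform grid, where g is a unit-height raised-cosine bump of FWHM
#' `l_mean` truncated at one width either side. Overlapping beads add
#' linearly in radius, so local maxima stay at the drawn positions for
#' moderate amplitudes.
#'
#' @param positions Output of [generate_restriction_positions()] (or any
#'   increasing positions with an `"L"` attribute).
#' @param spec A [bead_spec()].
#' @param dz Grid spacing (um); must resolve the bead width
#'   (`dz <= l_mean / 5`).
#' @param L Axon length (um); defaults to the `"L"` attribute of
#'   `positions`.
#' @return A [radius_profile()].
#' @export
generate_radius_profile <- function(positions, spec, dz = 0.1,
                                    L = attr(positions, "L")) {
  stopifnot(inherits(spec, "bead_spec"))
  if (is.null(L)) {
    stop_axonwalk("`L` missing: pass it or use positions from the generator",
                  "axonwalk_error_invalid_spec")
  }
  if (dz > spec$l_mean / 5) {
    stop_axonwalk(
      sprintf("dz = %g um too coarse to resolve bead width %g um (need dz <= l_mean/5)",
              dz, spec$l_mean),
      "axonwalk_error_resolution"
    )
  }
  n <- max(1L, round(L / dz))
  z <- (seq_len(n) - 0.5) * dz
  bump_sum <- rep(0, n)
  for (zk in positions) {
    lo <- max(1L, ceiling((zk - spec$l_mean) / dz + 0.5))
    hi <- min(n, floor((zk + spec$l_mean) / dz + 0.5))
    if (lo <= hi) {
      idx <- lo:hi
      bump_sum[idx] <- bump_sum[idx] + bead_bump((z[idx] - zk) / spec$l_mean)
    }
  }
  radius_profile(spec$r0 * (1 + spec$amplitude * bump_sum), dz)
}

#' Rescale radius profiles to a common volume
#'
#' Each profile's radii are multiplied by `sqrt(V_bar / V_i)` so that every
#' axon ends up with the mean volume `V_bar` of the input set; the total
#' volume is conserved. The coefficient of variation of each profile's
#' radii is unchanged (the statistic is scale free).
#'
#' @param profiles A list of [radius_profile()] objects.
#' @return A list of volume-normalized `radius_profile`s.
#' @export
normalize_volumes <- function(profiles) {
  if (length(profiles) == 0L) {
    stop_axonwalk("empty profile list", "axonwalk_error_invalid_spec")
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "radius_profile")))
  vols <- vapply(profiles, profile_volume, numeric(1))
  v_bar <- mean(vols)
  purrr::map2(profiles, vols, function(p, v) {
    radius_profile(p$r * sqrt(v_bar / v), profile_dz(p))
  })
}

#' Labeled substrate volume
#'
#' A 3-D voxel grid with compartment labels 0 (exterior), 1 (axoplasm),
#' 2 (mitochondrion) and isotropic voxel size `h` (um). Voxel centres sit
#' at `(i - 1/2) h` along each axis (0-based geometric origin at the grid
#' corner); the fiber axis is z (third index).
#'
#' @param labels Integer 3-D array with values in `{0, 1, 2}`.
#' @param h Isotropic voxel size (um).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, h) {
  check_number(h, "h", lower = 1e-12)
  if (length(dim(labels)) != 3L) {
    stop_axonwalk("`labels` must be a 3-D array",
                  "axonwalk_error_invalid_volume")
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) {
    stop_axonwalk("labels must be 0 (exterior), 1 (axoplasm) or 2 (mitochondrion)",
                  "axonwalk_error_invalid_volume")
  }
  if (!any(labels == 1L)) {
    stop_axonwalk("volume has no axoplasm voxels",
                  "axonwalk_error_invalid_volume")
  }
  structure(list(labels = labels, h = h), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, h = %g um\n",
              d[1], d[2], d[3], x$h))
  cat(sprintf("  axoplasm %.3g um^3, mitochondria %.3g um^3\n",
              sum(x$labels == 1L) * x$h^3, sum(x$labels == 2L) * x$h^3))
  invisible(x)
}

#' Total intracellular volume of a labeled substrate
#'
#' @param vol A [labeled_volume()].
#' @return Volume of labels `{1, 2}` (um^3).
#' @export
volume_of <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  sum(vol$labels != 0L) * vol$h^3
}

#' Axon skeleton (undulation track)
#'
#' Transverse offsets of the axon axis as a function of z, stored as a
#' tibble with columns `z`, `x`, `y` (um). `sigma_s` records the Gaussian
#' smoothing scale applied along z.
#'
#' @param x,y Transverse offsets per grid point (um).
#' @param dz Grid spacing (um).
#' @param sigma_s Gaussian smoothing SD already applied (um).
#' @return A tibble of class `axon_skeleton`.
#' @export
axon_skeleton <- function(x, y, dz, sigma_s = 0) {
  check_number(dz, "dz", lower = 1e-12)
  check_number(sigma_s, "sigma_s", lower = 0)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  out <- tibble(z = (seq_along(x) - 0.5) * dz, x = as.numeric(x),
                y = as.numeric(y))
  structure(out, dz = dz, sigma_s = sigma_s,
            class = c("axon_skeleton", class(out)))
}

#' Generate a smooth undulating skeleton
#'
#' Harmonic undulation with random phases: each transverse coordinate is a
#' sinusoid of wavelength `wavelength` and RMS amplitude `amplitude`,
#' independently phased in x and y, then smoothed by a Gaussian of SD
#' `sigma_s`. A minimal but controllable model of axonal undulation.
#'
#' @param L Axon length (um).
#' @param amplitude RMS transverse displacement (um).
#' @param wavelength Undulation wavelength (um).
#' @param dz Grid spacing (um).
#' @param sigma_s Gaussian smoothing SD (um).
#' @param seed Integer seed.
#' @return An [axon_skeleton()].
#' @export
generate_skeleton <- function(L, amplitude = 0.5, wavelength = 20,
                              dz = 0.1, sigma_s = 1, seed = 1L) {
  n <- max(2L, round(L / dz))
  z <- (seq_len(n) - 0.5) * dz
  local_seed(seed, {
    phx <- stats::runif(1, 0, 2 * pi)
    phy <- stats::runif(1, 0, 2 * pi)
    x <- amplitude * sqrt(2) * sin(2 * pi * z / wavelength + phx)
    y <- amplitude * sqrt(2) * sin(2 * pi * z / wavelength + phy)
    axon_skeleton(gaussian_smooth(x, sigma_s, dz),
                  gaussian_smooth(y, sigma_s, dz), dz, sigma_s)
  })
}

#' Voxelize a (possibly undulating) tube onto a labeled grid
#'
#' A voxel is labeled axoplasm iff its centre lies inside the tube: at the
#' voxel's z slice, the transverse distance from the skeleton axis must not
#' exceed r(z). Cross-sections are taken perpendicular to z. The grid is
#' padded by two exterior voxels in x and y; the z extent equals the
#' profile length (so mirror boundary conditions can extend it seamlessly).
#'
#' @param profile A [radius_profile()].
#' @param skeleton Optional [axon_skeleton()] on a compatible grid; `NULL`
#'   means a straight axis.
#' @param h Isotropic voxel size (um); must satisfy `h <= min(r) / 3`.
#' @return A [labeled_volume()].
#' @examples
#' prof <- radius_profile(rep(1, 100), dz = 0.1)
#' vox <- voxelize(prof, h = 0.1)
#' @export
voxelize <- function(profile, skeleton = NULL, h = 0.1) {
  stopifnot(inherits(profile, "radius_profile"))
  if (h > min(profile$r) / 3) {
    stop_axonwalk(
      sprintf("h = %g um too coarse for minimum radius %g um (need h <= r/3)",
              h, min(profile$r)),
      "axonwalk_error_resolution"
    )
  }
  L <- profile_length(profile)
  nz <- max(1L, round(L / h))
  zc <- (seq_len(nz) - 0.5) * h
  r_z <- stats::approx(profile$z, profile$r, xout = zc, rule = 2)$y
  if (is.null(skeleton)) {
    x_z <- rep(0, nz); y_z <- rep(0, nz)
  } else {
    x_z <- stats::approx(skeleton$z, skeleton$x, xout = zc, rule = 2)$y
    y_z <- stats::approx(skeleton$z, skeleton$y, xout = zc, rule = 2)$y
  }
  pad <- 2 * h
  half_x <- max(abs(x_z) + r_z) + pad
  half_y <- max(abs(y_z) + r_z) + pad
  nx <- 2L * ceiling(half_x / h)
  ny <- 2L * ceiling(half_y / h)
  cx <- nx * h / 2
  cy <- ny * h / 2
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  labels <- array(0L, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    dx2 <- (xc - (cx + x_z[k]))^2
    dy2 <- (yc - (cy + y_z[k]))^2
    labels[, , k] <- as.integer(outer(dx2, dy2, `+`) <= r_z[k]^2)
  }
  labeled_volume(labels, h)
}

# Voxelize a constant-radius tube around a 3-D polyline skeleton, with
# cross-sections perpendicular to the (local) skeleton: a voxel is inside
# iff its distance to the polyline is <= R. Used for the undulation-only
# scenario, where the tube must have constant cross-sectional area.
voxelize_canal <- function(skeleton, R, h, half_x = NULL, half_y = NULL) {
  dz <- attr(skeleton, "dz", exact = TRUE)
  nz <- max(1L, round(max(skeleton$z) + dz / 2) / h) # grid in h units
  L <- nrow(skeleton) * dz
  nz <- max(1L, round(L / h))
  zc <- (seq_len(nz) - 0.5) * h
  x_z <- stats::approx(skeleton$z, skeleton$x, xout = zc, rule = 2)$y
  y_z <- stats::approx(skeleton$z, skeleton$y, xout = zc, rule = 2)$y
  pad <- 2 * h
  if (is.null(half_x)) half_x <- max(abs(x_z)) + R + pad
  if (is.null(half_y)) half_y <- max(abs(y_z)) + R + pad
  nx <- 2L * ceiling(half_x / h)
  ny <- 2L * ceiling(half_y / h)
  cx <- nx * h / 2
  cy <- ny * h / 2
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  # Distance from a voxel centre to the polyline: minimum over segments in a
  # z window of +-(R + window) around the voxel's slice.
  labels <- array(0L, dim = c(nx, ny, nz))
  pts <- cbind(cx + x_z, cy + y_z, zc)
  win <- ceiling((R + 2 * h) / h)
  for (k in seq_len(nz)) {
    ks <- max(1L, k - win):min(nz, k + win)
    grid_x <- rep(xc, times = ny)
    grid_y <- rep(yc, each = nx)
    d2min <- rep(Inf, nx * ny)
    for (j in ks) {
      d2 <- (grid_x - pts[j, 1])^2 + (grid_y - pts[j, 2])^2 +
        (zc[k] - pts[j, 3])^2
      d2min <- pmin(d2min, d2)
    }
    labels[, , k] <- as.integer(matrix(d2min <= R^2, nx, ny))
  }
  labeled_volume(labels, h)
}

#' Build one of the canonical simulation scenarios
#'
#' Turns an axon geometry into a labeled substrate volume under one of five
#' constructions:
#' \describe{
#'   \item{`"I"`}{full geometry (caliber variation + undulation) with
#'     mitochondria inclusions labeled 2; requires `props` and `seed`.}
#'   \item{`"II"`}{same geometry, no mitochondria (single compartment).}
#'   \item{`"III"`}{caliber variation only: an axially symmetric tube with
#'     the same cross-sectional area A(z) around a straight axis.}
#'   \item{`"IV"`}{undulation only: a constant-area tube following the
#'     Gaussian-smoothed (`sigma_s = 1` um) skeleton, radius calibrated so
#'     the voxelized volume matches the source volume to 1e-3 relative.}
#'   \item{`"straight"`}{a straight constant-radius cylinder of the same
#'     total volume.}
#' }
#'
#' @param profile A [radius_profile()] (caliber source). Alternatively a
#'   [labeled_volume()], from which the equivalent-radius profile and the
#'   centroid skeleton are derived.
#' @param scenario One of `"I"`, `"II"`, `"III"`, `"IV"`, `"straight"`.
#' @param skeleton Optional [axon_skeleton()] (undulation source) used for
#'   scenarios I, II and IV.
#' @param props A [compartment_props()] (scenario I only).
#' @param h Voxel size (um).
#' @param seed Seed for mitochondria placement (scenario I only).
#' @param sigma_s Skeleton smoothing SD for scenario IV (um).
#' @return A [labeled_volume()].
#' @export
make_scenario <- function(profile, scenario = c("I", "II", "III", "IV",
                                                "straight"),
                          skeleton = NULL, props = compartment_props(),
                          h = 0.1, seed = 1L, sigma_s = 1) {
  scenario <- match.arg(scenario)
  if (inherits(profile, "labeled_volume")) {
    cs <- cross_section_series(profile)
    src_vol <- volume_of(profile)
    dz_src <- profile$h
    ok <- !is.na(cs$r_eq) & cs$r_eq > 0
    prof <- radius_profile(cs$r_eq[ok], dz_src)
    if (is.null(skeleton)) {
      skeleton <- axon_skeleton(cs$cx[ok] - mean(cs$cx[ok]),
                                cs$cy[ok] - mean(cs$cy[ok]), dz_src)
    }
    profile <- prof
  }
  stopifnot(inherits(profile, "radius_profile"))
  L <- profile_length(profile)
  V <- profile_volume(profile)
  switch(
    scenario,
    "straight" = voxelize(radius_profile(rep(sqrt(V / (pi * L)),
                                             nrow(profile)),
                                         profile_dz(profile)), NULL, h),
    "III" = voxelize(profile, NULL, h),
    "II" = voxelize(profile, skeleton, h),
    "I" = {
      vol <- voxelize(profile, skeleton, h)
      place_mitochondria(vol, profile, props, seed)
    },
    "IV" = {
      if (is.null(skeleton)) {
        stop_axonwalk("scenario IV requires a skeleton",
                      "axonwalk_error_invalid_spec")
      }
      sk <- axon_skeleton(
        gaussian_smooth(skeleton$x, sigma_s, attr(skeleton, "dz")),
        gaussian_smooth(skeleton$y, sigma_s, attr(skeleton, "dz")),
        attr(skeleton, "dz"), sigma_s
      )
      calibrate_canal(sk, V, h)
    }
  )
}

# Find the tube radius whose voxelized canal volume matches `target` to
# 1e-3 relative, by bisection. Voxel granularity h^3 is far below the
# tolerance for any realistic axon, so the bisection converges.
calibrate_canal <- function(skeleton, target, h, tol = 1e-3) {
  arc <- sum(sqrt(diff(skeleton$x)^2 + diff(skeleton$y)^2 +
                  diff(skeleton$z)^2)) + attr(skeleton, "dz")
  r_guess <- sqrt(target / (pi * arc))
  lo <- 0.7 * r_guess
  hi <- 1.3 * r_guess
  half_x <- max(abs(skeleton$x)) + hi + 2 * h
  half_y <- max(abs(skeleton$y)) + hi + 2 * h
  best <- NULL
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    vol <- voxelize_canal(skeleton, mid, h, half_x, half_y)
    v <- volume_of(vol)
    if (abs(v - target) / target < tol) return(vol)
    if (v < target) lo <- mid else hi <- mid
    best <- vol
  }
  warn("canal volume calibration did not reach 1e-3 relative tolerance")
  best
}

#' Place mitochondria inclusions inside a substrate
#'
#' Adds rod-shaped inclusions (cylinders of radius `0.45` of the mean
#' radius, length uniform in 1--2 um, axis along z) to axoplasm voxels
#' until the mitochondrial volume fraction reaches `props$f_m`. The rod
#' caliber makes a mitochondrion occupy roughly a fifth of the local
#' cross-section, so a 6% volume fraction occupies roughly a third of the
#' axon length, as observed in segmented axons. Rod centres are drawn by
#' rejection sampling with per-slice acceptance proportional to A(z)^2
#' (the mitochondrial volume per unit length grows quadratically with the
#' local diameter), reproducing the association of mitochondria with
#' larger calibers.
#'
#' @param vol A [labeled_volume()].
#' @param profile The [radius_profile()] the volume was built from (supplies
#'   the baseline radius for the rod caliber).
#' @param props A [compartment_props()]; `props$f_m` is the target fraction.
#' @param seed Integer seed.
#' @return A [labeled_volume()] with label-2 inclusions.
#' @export
place_mitochondria <- function(vol, profile, props, seed) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(props, "compartment_props"))
  f_m <- props$f_m
  if (f_m >= 0.5) {
    stop_axonwalk("f_m must be < 0.5", "axonwalk_error_invalid_spec")
  }
  if (f_m == 0) return(vol)
  labels <- vol$labels
  h <- vol$h
  d <- dim(labels)
  slice_counts <- vapply(seq_len(d[3]),
                         function(k) sum(labels[, , k] != 0L), numeric(1))
  if (all(slice_counts == 0)) {
    stop_axonwalk("volume has no axoplasm", "axonwalk_error_invalid_volume")
  }
  r_rod <- 0.45 * mean(profile$r)
  rod_half_w <- ceiling(r_rod / h)
  total <- sum(slice_counts)
  target <- f_m * total
  local_seed(seed, {
    placed <- 0
    prev <- NULL
    added <- 0L
    guard <- 0L
    while (placed < target && guard < 10000L) {
      guard <- guard + 1L
      k0 <- sample.int(d[3], 1L, prob = slice_counts^2)
      len <- stats::runif(1, 1, 2)
      nk <- max(1L, round(len / h))
      ks <- k0:min(d[3], k0 + nk - 1L)
      # rod axis at the in-axon centroid of the seed slice
      idx <- which(labels[, , k0] != 0L, arr.ind = TRUE)
      ci <- round(mean(idx[, 1])); cj <- round(mean(idx[, 2]))
      is_ <- max(1L, ci - rod_half_w):min(d[1], ci + rod_half_w)
      js_ <- max(1L, cj - rod_half_w):min(d[2], cj + rod_half_w)
      xc <- (is_ - 0.5) * h; yc <- (js_ - 0.5) * h
      disc <- outer((xc - (ci - 0.5) * h)^2, (yc - (cj - 0.5) * h)^2,
                    `+`) <= r_rod^2
      prev <- labels
      added <- 0L
      for (k in ks) {
        sl <- labels[is_, js_, k]
        hit <- disc & sl == 1L
        added <- added + sum(hit)
        sl[hit] <- 2L
        labels[is_, js_, k] <- sl
      }
      placed <- placed + added
    }
    # keep the count closest to the target: revert the last rod if the
    # undershoot without it beats the overshoot with it
    if (!is.null(prev) && placed > target &&
        (placed - target) > (target - (placed - added))) {
      labels <- prev
    }
  })
  labeled_volume(labels, h)
}

#' Sample axon directions from a Watson distribution
#'
#' Draws `n` unit vectors from the axially symmetric Watson distribution
#' about the z axis, with density proportional to `exp(kappa * cos^2 psi)`.
#' `kappa = Inf` returns the z axis itself; `kappa = 0` is uniform on the
#' sphere. Sampling is by rejection on `cos psi`.
#'
#' @param kappa Concentration parameter, `>= 0` or `Inf`.
#' @param n Number of directions.
#' @param seed Integer seed.
#' @return A tibble of class `orientation_set` with columns `x`, `y`, `z`
#'   (unit vectors) and attributes `kappa` and `theta` (the aggregate
#'   dispersion angle from [kappa_to_theta()], degrees).
#' @examples
#' sample_watson(4.7, 1000, seed = 1)
#' @export
sample_watson <- function(kappa, n, seed) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop_axonwalk("kappa must be >= 0 (possibly Inf)",
                  "axonwalk_error_invalid_spec")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_axonwalk("n must be >= 1", "axonwalk_error_invalid_spec")
  }
  n <- as.integer(n)
  if (is.infinite(kappa)) {
    out <- tibble(x = rep(0, n), y = rep(0, n), z = rep(1, n))
  } else {
    out <- local_seed(seed, {
      u <- numeric(0)
      while (length(u) < n) {
        cand <- stats::runif(4L * n, -1, 1)
        acc <- stats::runif(4L * n) < exp(kappa * (cand^2 - 1))
        u <- c(u, cand[acc])
      }
      u <- u[seq_len(n)]
      phi <- stats::runif(n, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - u^2))
      tibble(x = s * cos(phi), y = s * sin(phi), z = u)
    })
  }
  structure(out, kappa = kappa, theta = kappa_to_theta(kappa),
            class = c("orientation_set", class(out)))
}

#' Aggregate dispersion angle of a Watson distribution
#'
#' Computes `theta = acos(sqrt(<cos^2 psi>))` in degrees, where the
#' orientation average is taken under the Watson density
#' `exp(kappa cos^2 psi)` by deterministic quadrature:
#' `<cos^2> = int_0^1 u^2 e^(kappa u^2) du / int_0^1 e^(kappa u^2) du`.
#'
#' @param kappa Concentration parameter(s), `>= 0` or `Inf`; vectorized.
#' @return Dispersion angle(s) in degrees (0 for `kappa = Inf`, 54.7356 for
#'   `kappa = 0`).
#' @examples
#' kappa_to_theta(c(Inf, 15.4, 4.7, 1.65, 0))
#' @export
kappa_to_theta <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k) || k < 0) {
      stop_axonwalk("kappa must be >= 0", "axonwalk_error_invalid_spec")
    }
    acos(sqrt(watson_cos2(k))) * 180 / pi
  }, numeric(1))
}

#' Mean squared direction cosine under a Watson distribution
#'
#' @inheritParams kappa_to_theta
#' @return `<cos^2 psi>` in `[1/3, 1]` for `kappa >= 0`.
#' @export
watson_cos2 <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k) || k < 0) {
      stop_axonwalk("kappa must be >= 0", "axonwalk_error_invalid_spec")
    }
    if (is.infinite(k)) return(1)
    # rescale by exp(-k) so the integrand stays bounded for large kappa
    num <- integrate(function(u) u^2 * exp(k * (u^2 - 1)), 0, 1,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
    den <- integrate(function(u) exp(k * (u^2 - 1)), 0, 1,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
    num / den
  }, numeric(1))
}
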