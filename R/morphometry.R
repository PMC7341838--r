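#' Per-slice cross-section series of a labeled volume
#'
#' For every z slice, the cross-sectional area A(z) (counting labels 1 and
#' 2), the in-axon centroid, and the equivalent radius `r_eq = sqrt(A/pi)`.
#' Slices with no in-axon voxels are flagged as gaps (`in_axon = FALSE`).
#'
#' @param vol A [labeled_volume()].
#' @return A tibble with columns `z`, `area` (um^2), `cx`, `cy` (um),
#'   `r_eq` (um), `n_vox`, `in_axon`.
#' @export
cross_section_series <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  d <- dim(vol$labels)
  h <- vol$h
  xc <- (seq_len(d[1]) - 0.5) * h
  yc <- (seq_len(d[2]) - 0.5) * h
  rows <- purrr::map(seq_len(d[3]), function(k) {
    sl <- vol$labels[, , k] != 0L
    n <- sum(sl)
    if (n == 0L) {
      tibble(z = (k - 0.5) * h, area = 0, cx = NA_real_, cy = NA_real_,
             r_eq = NA_real_, n_vox = 0L, in_axon = FALSE)
    } else {
      tibble(z = (k - 0.5) * h, area = n * h^2,
             cx = sum(rowSums(sl) * xc) / n,
             cy = sum(colSums(sl) * yc) / n,
             r_eq = sqrt(n * h^2 / pi), n_vox = n, in_axon = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Caliber statistics of a radius profile
#'
#' Mean radius, SD and coefficient of variation CV(r) = sd(r) / mean(r),
#' together with the cross-sectional area series.
#'
#' @param profile A [radius_profile()].
#' @return A one-row tibble with `r_mean`, `r_sd`, `cv_r`, `area_mean`.
#' @export
caliber_stats <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  tibble(r_mean = mean(profile$r), r_sd = sd(profile$r),
         cv_r = sd(profile$r) / mean(profile$r),
         area_mean = mean(pi * profile$r^2))
}

#' Concatenate volume-normalized profiles in seeded random order
#'
#' @param profiles A list of [radius_profile()]s sharing a grid spacing
#'   (normally the output of [normalize_volumes()]).
#' @param seed Integer seed for the random permutation.
#' @return A single [radius_profile()] of total length equal to the sum of
#'   the input lengths.
#' @export
concatenate_profiles <- function(profiles, seed = 1L) {
  if (length(profiles) == 0L) {
    stop_axonwalk("empty profile list", "axonwalk_error_invalid_spec")
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "radius_profile")))
  dzs <- vapply(profiles, profile_dz, numeric(1))
  if (diff(range(dzs)) > 1e-12) {
    stop_axonwalk("profiles must share a grid spacing",
                  "axonwalk_error_invalid_spec")
  }
  ord <- local_seed(seed, sample.int(length(profiles)))
  radius_profile(unlist(lapply(profiles[ord], function(p) p$r)), dzs[1])
}

new_power_spectrum <- function(k, gamma, a_mean_area, flag) {
  out <- tibble(k = k, gamma = gamma)
  structure(out, a_mean_area = a_mean_area, flag = flag,
            class = c("power_spectrum", class(out)))
}

#' One-dimensional structural power spectrum of caliber variation
#'
#' Reduces the axially symmetric density built from a radius profile to the
#' 1-d power spectrum `Gamma(k_z) = |A(k_z)|^2 / (V * A_bar)`, where
#' `A(k_z)` is the discrete Fourier transform of the cross-sectional area
#' series `A(z) = pi r(z)^2`, `V` the axon volume and `A_bar` the mean
#' area. By default the mean area is subtracted first (fluctuation
#' spectrum): the finite-length spectral leakage of the mean otherwise
#' swamps the low-k plateau that diagnoses short-range disorder.
#'
#' The low-k behaviour classifies the disorder: a plateau (`p = 0`) means
#' restrictions are placed with a finite correlation length and implies the
#' `t^(-1/2)` tail of the time-dependent axial diffusivity.
#'
#' @param profile A [radius_profile()].
#' @param subtract_mean Subtract the mean area before transforming
#'   (default `TRUE`).
#' @return A tibble of class `power_spectrum` with columns `k` (rad/um,
#'   positive frequencies up to Nyquist) and `gamma` (um).
#' @export
power_spectrum_density <- function(profile, subtract_mean = TRUE) {
  stopifnot(inherits(profile, "radius_profile"))
  dz <- profile_dz(profile)
  A <- pi * profile$r^2
  n <- length(A)
  L <- n * dz
  a_bar <- mean(A)
  v <- sum(A) * dz
  f <- if (subtract_mean) A - a_bar else A
  A_k <- fft(f) * dz
  m <- seq_len(floor(n / 2))          # k > 0 up to Nyquist
  k <- 2 * pi * m / L
  gamma <- Mod(A_k[m + 1L])^2 / (v * a_bar)
  new_power_spectrum(k, gamma, a_bar, "of-density")
}

#' Power spectrum of restriction positions
#'
#' Structure factor of the sum-of-delta-functions density of local caliber
#' maxima, `Gamma_pos(k) = |sum_j exp(-i k z_j)|^2 / N`, evaluated on the
#' grid `k = 2 pi m / L`. Normalized so the low-k plateau tends to
#' `(sigma_a / a_mean)^2` for renewal (independent-spacing) placement:
#' periodic positions give 0 and Poisson positions give 1.
#'
#' @param positions Increasing restriction positions (um) with an `"L"`
#'   attribute (as from [generate_restriction_positions()]), or pass `L`.
#' @param L Domain length (um).
#' @return A tibble of class `power_spectrum` (dimensionless `gamma`).
#' @export
position_spectrum <- function(positions, L = attr(positions, "L")) {
  n <- length(positions)
  if (n < 10L) {
    stop_axonwalk("need at least 10 positions", "axonwalk_error_invalid_spec")
  }
  if (is.null(L)) L <- max(positions)
  m <- seq_len(floor(n / 2))
  k <- 2 * pi * m / L
  gamma <- vapply(k, function(kk) {
    Mod(sum(exp(-1i * kk * positions)))^2 / n
  }, numeric(1))
  new_power_spectrum(k, gamma, NA_real_, "of-positions")
}

#' Low-k plateau level and structural exponent of a spectrum
#'
#' Averages the spectrum over the low-k window `(k_min, k_max)` for the
#' plateau, and regresses `log(gamma)` on `log(k)` over the same window for
#' the structural exponent p. `|p| < 0.3` is reported as consistent with
#' short-range disorder (a genuine plateau).
#'
#' @param spectrum A `power_spectrum` tibble.
#' @param k_max Upper edge of the fit window (rad/um). The default
#'   `0.5 / a_mean` keeps the window well below the bead-spacing scale
#'   `2 pi / a_mean`.
#' @param a_mean Mean restriction spacing (um), used only for the default
#'   `k_max`.
#' @param k_min Lower edge; defaults to the smallest available k.
#' @return A one-row tibble with `plateau`, `p`, `short_range`, `n_k`.
#' @export
estimate_plateau_and_p <- function(spectrum, k_max = NULL, a_mean = 5.70,
                                   k_min = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (is.null(k_max)) k_max <- 0.5 / a_mean
  if (is.null(k_min)) k_min <- min(spectrum$k) * (1 - 1e-9)
  win <- spectrum$k >= k_min & spectrum$k <= k_max
  if (sum(win) < 5L) {
    stop_axonwalk("fewer than 5 spectrum points in the low-k window",
                  "axonwalk_error_invalid_spec")
  }
  kk <- spectrum$k[win]
  gg <- spectrum$gamma[win]
  plateau <- mean(gg)
  pos <- gg > 0
  p <- if (sum(pos) >= 2L) {
    unname(coef(lm(log(gg[pos]) ~ log(kk[pos])))[2])
  } else {
    NA_real_
  }
  tibble(plateau = plateau, p = p, short_range = is.finite(p) && abs(p) < 0.3,
         n_k = sum(win))
}

#' Predicted low-k plateau for short-range disorder
#'
#' Closed-form normalized plateau of the 1-d caliber power spectrum for
#' renewal bead placement:
#' `Gamma / a_mean = (a_sd^2 / a_mean^2) * (l_mean^2 / a_mean^2)`
#' (dimensionless). The un-normalized plateau (um) is this times `a_mean`.
#'
#' @param a_mean Mean restriction spacing (um).
#' @param a_sd SD of the spacing (um).
#' @param l_mean Average restriction width (um).
#' @return Normalized plateau `Gamma / a_mean` (dimensionless).
#' @examples
#' plateau_short_range(5.70, 2.88, 5.6)  # ~0.25
#' @export
plateau_short_range <- function(a_mean, a_sd, l_mean) {
  check_number(a_mean, "a_mean", lower = 1e-12)
  check_number(a_sd, "a_sd", lower = 0)
  check_number(l_mean, "l_mean", lower = 1e-12)
  (a_sd^2 / a_mean^2) * (l_mean^2 / a_mean^2)
}

#' Average restriction width from an observed plateau
#'
#' Inverts the short-range-disorder plateau relation:
#' `l_mean = (a_mean^2 / a_sd) * sqrt(plateau)`.
#'
#' @param plateau Normalized plateau `Gamma / a_mean` (dimensionless).
#' @param a_mean Mean restriction spacing (um).
#' @param a_sd SD of the spacing (um); must be positive.
#' @return Average restriction width (um).
#' @examples
#' width_from_plateau(0.25, 5.70, 2.88)  # ~5.6
#' @export
width_from_plateau <- function(plateau, a_mean, a_sd) {
  check_number(plateau, "plateau", lower = 0)
  check_number(a_mean, "a_mean", lower = 1e-12)
  if (!is.numeric(a_sd) || length(a_sd) != 1L || is.na(a_sd) || a_sd <= 0) {
    stop_axonwalk("the inverse relation is undefined for a_sd = 0",
                  "axonwalk_error_invalid_spec")
  }
  (a_mean^2 / a_sd) * sqrt(plateau)
}

#' Locate restrictions (local caliber maxima) in a profile
#'
#' Smooths the radius series with a centred moving average of width
#' `smoothing` (um) and finds interior local maxima; plateau ties are
#' resolved to the leftmost point. Spacing statistics come from successive
#' maxima; the average restriction width is estimated by inverting the
#' plateau relation on the profile's own caliber power spectrum
#' (`NA` when the spacing SD is degenerate).
#'
#' @param profile A [radius_profile()].
#' @param smoothing Moving-average window (um), default 1.
#' @return A list of class `restriction_stats` with elements `positions`
#'   (um), `a_mean`, `a_sd`, `l_est` (um) and `n`.
#' @export
find_restrictions <- function(profile, smoothing = 1) {
  stopifnot(inherits(profile, "radius_profile"))
  dz <- profile_dz(profile)
  w <- max(1L, round(smoothing / dz))
  if (w %% 2L == 0L) w <- w + 1L
  r_s <- as.numeric(stats::filter(profile$r, rep(1 / w, w), sides = 2))
  n <- length(r_s)
  idx <- which(!is.na(r_s))
  # leftmost-tie local maxima: strictly above the previous point, at least
  # as high as the next
  core <- idx[idx > min(idx) & idx < max(idx)]
  is_max <- r_s[core] > r_s[core - 1L] & r_s[core] >= r_s[core + 1L]
  peaks <- core[is_max]
  if (length(peaks) < 2L) {
    stop_axonwalk("no interior maxima found", "axonwalk_error_no_maxima")
  }
  pos <- profile$z[peaks]
  gaps <- diff(pos)
  a_mean <- mean(gaps)
  a_sd <- sd(gaps)
  l_est <- if (is.finite(a_sd) && a_sd > 1e-9 * a_mean) {
    tryCatch({
      ps <- power_spectrum_density(profile)
      pl <- estimate_plateau_and_p(ps, a_mean = a_mean)
      width_from_plateau(pl$plateau / a_mean, a_mean, a_sd)
    }, axonwalk_error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(
    list(positions = pos, a_mean = a_mean, a_sd = a_sd, l_est = l_est,
         n = length(pos)),
    class = "restriction_stats"
  )
}

#' @export
print.restriction_stats <- function(x, ...) {
  cat(sprintf("<restriction_stats> %d maxima: a = %.3g um (SD %.3g um), l_est = %.3g um\n",
              x$n, x$a_mean, x$a_sd, x$l_est))
  invisible(x)
}
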