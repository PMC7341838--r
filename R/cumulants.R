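# Exponent table for the 15 stored fourth-moment monomials x^a y^b z^c and
# their multinomial contraction coefficients 4!/(a! b! c!).
fourth_exponents <- cbind(
  a = c(4, 3, 3, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0, 0),
  b = c(0, 1, 0, 2, 1, 0, 3, 2, 1, 0, 4, 3, 2, 1, 0),
  c = c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 4)
)

check_unit <- function(n, tol = 1e-6) {
  if (!is.numeric(n) || length(n) != 3L ||
      abs(sqrt(sum(n^2)) - 1) > tol) {
    stop_axonwalk("direction must be a unit 3-vector",
                  "axonwalk_error_invalid_direction")
  }
  n
}

# Directional second and fourth displacement moments <s^2>, <s^4> from a
# moment record, s = n . x.
contract_moments <- function(rec, direction) {
  stopifnot(inherits(rec, "moment_record"))
  n <- check_unit(direction)
  m2 <- as.matrix(rec[paste0("m2_", moment_cols2)])
  s2 <- n[1]^2 * m2[, "m2_xx"] + n[2]^2 * m2[, "m2_yy"] +
    n[3]^2 * m2[, "m2_zz"] +
    2 * (n[1] * n[2] * m2[, "m2_xy"] + n[1] * n[3] * m2[, "m2_xz"] +
           n[2] * n[3] * m2[, "m2_yz"])
  m4 <- as.matrix(rec[paste0("m4_", moment_cols4)])
  coefs <- apply(fourth_exponents, 1, function(e) {
    (24 / (factorial(e[1]) * factorial(e[2]) * factorial(e[3]))) *
      n[1]^e[1] * n[2]^e[2] * n[3]^e[3]
  })
  s4 <- drop(m4 %*% coefs)
  tibble(t = rec$t, s2 = s2, s4 = s4)
}

match_times <- function(rec, t) {
  if (is.null(t)) return(seq_len(nrow(rec)))
  idx <- vapply(t, function(tt) {
    i <- which(abs(rec$t - tt) <= 1e-6 * max(1, tt))
    if (length(i) == 0L) {
      stop_axonwalk(sprintf("t = %g ms was not sampled", tt),
                    "axonwalk_error_time_not_sampled")
    }
    i[1]
  }, integer(1))
  idx
}

#' Apparent diffusivity along a direction
#'
#' `D(t, n) = <s^2> / (2 t)` with `<s^2> = n_i n_j <x_i x_j>`, the
#' projection of the weighted second displacement moment tensor onto the
#' unit direction `n`.
#'
#' @param rec A `moment_record` from [run_walk()] or [run_walk_free()].
#' @param direction Unit 3-vector.
#' @param t Times (ms) among the record's sampled times; `NULL` (default)
#'   uses all of them.
#' @return A tibble with columns `t`, `D` (um^2/ms).
#' @export
apparent_D <- function(rec, direction, t = NULL) {
  idx <- match_times(rec, t)
  cm <- contract_moments(rec, direction)[idx, ]
  tibble(t = cm$t, D = cm$s2 / (2 * cm$t))
}

#' Apparent kurtosis along a direction
#'
#' `K(t, n) = <s^4> / <s^2>^2 - 3`, with `<s^4>` the full directional
#' contraction of the weighted fourth displacement moment tensor. Zero for
#' Gaussian displacements; bounded below by -2.
#'
#' @inheritParams apparent_D
#' @return A tibble with columns `t`, `K` (dimensionless).
#' @export
apparent_K <- function(rec, direction, t = NULL) {
  idx <- match_times(rec, t)
  cm <- contract_moments(rec, direction)[idx, ]
  if (any(cm$s2 <= 0)) {
    stop_axonwalk("zero second moment; kurtosis undefined",
                  "axonwalk_error_degenerate")
  }
  tibble(t = cm$t, K = cm$s4 / cm$s2^2 - 3)
}

#' Reflect a direction about the z axis
#'
#' `n = 2 (n' . z) z - n'`: the mirror image of `n'` in the plane normal to
#' z, preserving the z component. Used to fold an axon's own-frame moments
#' into a dispersed bundle: drawing `n'` from the orientation distribution
#' and evaluating the axon's moments along the reflected direction gives
#' its contribution along the bundle axis, exactly like a light ray
#' reflecting off a mirror normal to z.
#'
#' @param direction Unit 3-vector (or matrix of row vectors).
#' @return The reflected unit vector(s), same shape as the input.
#' @examples
#' reflect_direction(c(1, 0, 0))      # -> (-1, 0, 0)
#' reflect_direction(c(0, 0, 1))      # -> (0, 0, 1)
#' @export
reflect_direction <- function(direction) {
  if (is.matrix(direction)) {
    return(t(apply(direction, 1, reflect_direction)))
  }
  n <- check_unit(direction)
  c(-n[1], -n[2], n[3])
}

#' Per-axon cumulant series
#'
#' Packages one axon's time-resolved diffusivity and kurtosis with its
#' volume fraction, ready for ensemble averaging.
#'
#' @param rec A `moment_record`.
#' @param direction Unit 3-vector along which to project.
#' @param f Volume fraction of this axon in the ensemble.
#' @param id Axon identifier.
#' @return A tibble with columns `axon`, `f`, `t`, `D`, `K`.
#' @export
axon_cumulants <- function(rec, direction, f = 1, id = 1L) {
  D <- apparent_D(rec, direction)
  K <- apparent_K(rec, direction)
  tibble(axon = id, f = f, t = D$t, D = D$D, K = K$K)
}

check_fractions <- function(axons) {
  fr <- dplyr::distinct(axons, .data$axon, .data$f)
  if (abs(sum(fr$f) - 1) > 1e-8) {
    stop_axonwalk("volume fractions must sum to 1",
                  "axonwalk_error_fractions")
  }
  invisible(fr)
}

#' Ensemble (volume-weighted) diffusivity
#'
#' `D(t) = sum_i f_i D_i(t)`, the volume-fraction-weighted mean of the
#' per-axon diffusivities.
#'
#' @param axons A tibble with columns `axon`, `f`, `t`, `D` (and optionally
#'   `K`), e.g. rows of [axon_cumulants()] bound together.
#' @return A tibble with columns `t`, `D`.
#' @export
ensemble_D <- function(axons) {
  check_fractions(axons)
  axons |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(D = sum(.data$f * .data$D), .groups = "drop")
}

#' Ensemble (volume-weighted) kurtosis
#'
#' `K(t) = (1 / D^2) sum_i [ 3 f_i (D_i - D)^2 + f_i D_i^2 K_i ]`: the
#' inter-compartment variance term plus the intra-compartment kurtosis
#' term, reported separately in the `K_inter` and `K_intra` columns.
#'
#' @param axons A tibble with columns `axon`, `f`, `t`, `D`, `K`.
#' @return A tibble with columns `t`, `K`, `K_inter`, `K_intra`.
#' @export
ensemble_K <- function(axons) {
  check_fractions(axons)
  axons |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      .D = sum(.data$f * .data$D),
      K_inter = 3 * sum(.data$f * (.data$D - .D)^2) / .D^2,
      K_intra = sum(.data$f * .data$D^2 * .data$K) / .D^2,
      .groups = "drop"
    ) |>
    dplyr::mutate(K = .data$K_inter + .data$K_intra) |>
    dplyr::select("t", "K", "K_inter", "K_intra")
}

#' Synthesize dMRI signals from per-axon cumulants
#'
#' Cumulant-expansion signal of a non-exchanging axon ensemble:
#' `S(b, t) = sum_i f_i exp(-b D_i(t) + b^2 D_i(t)^2 K_i(t) / 6)`, with
#' `S(0, t) = 1` exactly. A warning is issued when any per-axon exponent is
#' non-monotone over the requested b range (`b > 3 / (D_i K_i)`), i.e.
#' when the truncated expansion leaves its validity range.
#'
#' @param axons A tibble with columns `axon`, `f`, `t`, `D`, `K`.
#' @param b Non-negative b-values (ms/um^2).
#' @return A tibble of class `signal_set` with columns `t`, `b`, `signal`.
#' @export
synthesize_signal <- function(axons, b) {
  check_fractions(axons)
  stopifnot(is.numeric(b), all(b >= 0))
  bmax <- max(b)
  lim <- with(axons, ifelse(K > 0, 3 / (D * K), Inf))
  if (any(bmax > lim)) {
    warn("b exceeds the cumulant-expansion validity bound 3/(D K) for some axons")
  }
  out <- tidyr::crossing(dplyr::distinct(axons, .data$t), b = b) |>
    dplyr::left_join(axons, by = "t", relationship = "many-to-many") |>
    dplyr::group_by(.data$t, .data$b) |>
    dplyr::summarise(
      signal = sum(.data$f * exp(-.data$b * .data$D +
                                   .data$b^2 * .data$D^2 * .data$K / 6)),
      .groups = "drop"
    )
  structure(out, class = c("signal_set", class(out)))
}

#' Weighted linear least-squares diffusivity/kurtosis fit
#'
#' Per diffusion time, fits `ln S = -b D + (b^2 / 6) D^2 K` as a linear
#' model in the coefficients `(D, D^2 K)` with weights `S^2` (the standard
#' weighting that undoes the log-transform noise amplification), and
#' returns the apparent diffusivity and kurtosis.
#'
#' @param signals A `signal_set` tibble (columns `t`, `b`, `signal`) with
#'   at least three distinct b-values including `b = 0` and all signals
#'   positive.
#' @return A tibble with columns `t`, `D`, `K`.
#' @export
fit_dki_wlls <- function(signals) {
  stopifnot(all(c("t", "b", "signal") %in% names(signals)))
  if (any(signals$signal <= 0)) {
    stop_axonwalk("signals must be positive", "axonwalk_error_invalid_spec")
  }
  bs <- unique(signals$b)
  if (length(bs) < 3L || !any(bs == 0)) {
    stop_axonwalk("need >= 3 distinct b-values including b = 0",
                  "axonwalk_error_invalid_spec")
  }
  signals |>
    dplyr::group_by(.data$t) |>
    dplyr::group_modify(function(df, key) {
      y <- log(df$signal)
      X <- cbind(-df$b, df$b^2 / 6)
      wts <- df$signal^2
      fit <- lm.wfit(X, y, wts)
      if (fit$rank < 2L) {
        stop_axonwalk("rank-deficient design in kurtosis fit",
                      "axonwalk_error_rank")
      }
      D <- unname(fit$coefficients[1])
      tibble(D = D, K = unname(fit$coefficients[2]) / D^2)
    }) |>
    dplyr::ungroup()
}
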