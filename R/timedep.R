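new_powerlaw_fit <- function(model, window, corrected, free_exponent = NULL) {
  cf <- coef(model)
  se <- sqrt(diag(suppressWarnings(vcov(model))))
  df <- model$df.residual
  # numerically exact data (zero residual variance at double precision)
  # makes the t-statistic meaningless: a zero slope is then a null result
  # (p = 1/2), a nonzero one infinitely significant
  scale <- max(abs(model$model[[1]]), 1e-300)
  sigma <- sqrt(sum(model$residuals^2) / max(df, 1L))
  tstat <- if (sigma > 1e-12 * scale) {
    cf[2] / se[2]
  } else if (abs(cf[2]) > 1e-10 * scale) {
    Inf
  } else {
    0
  }
  p_slope <- pt(tstat, df, lower.tail = FALSE)   # H1: positive slope
  structure(
    list(D_inf = unname(cf[1]), c = unname(cf[2]),
         c_prime = if (corrected) unname(cf[3]) else NA_real_,
         se_D_inf = unname(se[1]), se_c = unname(se[2]),
         se_c_prime = if (corrected) unname(se[3]) else NA_real_,
         p_slope = unname(p_slope), window = window, n = length(model$residuals),
         theta_exponent = 0.5, corrected = corrected,
         free_exponent = free_exponent, model = model),
    class = "powerlaw_fit"
  )
}

#' Fit the short-range-disorder power law to D(t)
#'
#' Ordinary least squares of `D(t) = D_inf + c / sqrt(t)` over the fit
#' window (default 20--80 ms, inside which the tail is established but the
#' substrate length does not yet bound the diffusion length). The dynamical
#' exponent is fixed at 1/2; the one-sided p-value tests the null of no
#' positive `1/sqrt(t)` slope.
#'
#' @param data A data frame with columns `t` (ms) and `D` (um^2/ms).
#' @param window Fit window `c(t_min, t_max)` in ms; `NULL` uses all rows.
#' @return An object of class `powerlaw_fit` with elements `D_inf`, `c`,
#'   their standard errors, `p_slope`, `window` and the underlying `lm`.
#'   Broom-style `tidy()` and `glance()` methods are provided.
#' @examples
#' d <- data.frame(t = 20:80)
#' d$D <- 1.25 + 0.426 / sqrt(d$t)
#' fit_power_law(d)
#' @export
fit_power_law <- function(data, window = c(20, 80)) {
  stopifnot(all(c("t", "D") %in% names(data)))
  if (!is.null(window)) {
    data <- data[data$t >= window[1] & data$t <= window[2], , drop = FALSE]
  } else {
    window <- range(data$t)
  }
  if (nrow(data) < 3L) {
    stop_axonwalk("need >= 3 points in the fit window",
                  "axonwalk_error_invalid_spec")
  }
  if (anyDuplicated(data$t)) {
    stop_axonwalk("duplicated times in the fit window",
                  "axonwalk_error_invalid_spec")
  }
  model <- lm(D ~ I(1 / sqrt(t)), data = data)
  new_powerlaw_fit(model, window, corrected = FALSE)
}

#' Power-law fit with a transverse 1/t correction
#'
#' Two-regressor least squares `D(t) = D_inf + c / sqrt(t) + c' / t`. The
#' `1/t` term absorbs the radially restricted diffusion of strongly tilted
#' axons that leaks into the bundle-axis projection in highly dispersed
#' bundles; with it, the fitted `c` returns to the `<cos^2 theta>` scaling.
#'
#' @inheritParams fit_power_law
#' @return A `powerlaw_fit` with the extra coefficient `c_prime` (um^2).
#' @export
fit_power_law_corrected <- function(data, window = NULL) {
  stopifnot(all(c("t", "D") %in% names(data)))
  if (!is.null(window)) {
    data <- data[data$t >= window[1] & data$t <= window[2], , drop = FALSE]
  } else {
    window <- range(data$t)
  }
  if (nrow(data) < 4L) {
    stop_axonwalk("need >= 4 points", "axonwalk_error_invalid_spec")
  }
  X <- cbind(1 / sqrt(data$t), 1 / data$t)
  if (kappa(cbind(1, X)) > 1e8) {
    warn("1/sqrt(t) and 1/t regressors are nearly collinear over this window")
  }
  model <- lm(D ~ I(1 / sqrt(t)) + I(1 / t), data = data)
  new_powerlaw_fit(model, window, corrected = TRUE)
}

#' Diagnostic fit with a free dynamical exponent
#'
#' Nonlinear fit `D(t) = D_inf + c * t^(-theta)` with `theta` free; a
#' diagnostic only — analysis and acceptance always fix `theta = 1/2`.
#'
#' @inheritParams fit_power_law
#' @return A list with `D_inf`, `c`, `theta` and the `nls` object.
#' @export
fit_power_law_free_exponent <- function(data, window = c(20, 80)) {
  stopifnot(all(c("t", "D") %in% names(data)))
  data <- data[data$t >= window[1] & data$t <= window[2], , drop = FALSE]
  start <- fit_power_law(data, window = NULL)
  model <- stats::nls(D ~ Dinf + cc * t^(-th), data = data,
                      start = list(Dinf = start$D_inf, cc = start$c, th = 0.5))
  cf <- coef(model)
  list(D_inf = unname(cf["Dinf"]), c = unname(cf["cc"]),
       theta = unname(cf["th"]), model = model)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit%s> D(t) = D_inf + c/sqrt(t)%s, window %g-%g ms\n",
              if (x$corrected) " +1/t" else "",
              if (x$corrected) " + c'/t" else "",
              x$window[1], x$window[2]))
  cat(sprintf("  D_inf = %.4g (SE %.2g) um^2/ms\n", x$D_inf, x$se_D_inf))
  cat(sprintf("  c     = %.4g (SE %.2g) um^2 ms^-1/2\n", x$c, x$se_c))
  if (x$corrected) {
    cat(sprintf("  c'    = %.4g (SE %.2g) um^2\n", x$c_prime, x$se_c_prime))
  }
  cat(sprintf("  one-sided p (positive slope) = %.3g, n = %d\n",
              x$p_slope, x$n))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  terms <- c("D_inf", "c", if (x$corrected) "c_prime")
  tibble(term = terms,
         estimate = c(x$D_inf, x$c, if (x$corrected) x$c_prime),
         std.error = c(x$se_D_inf, x$se_c, if (x$corrected) x$se_c_prime))
}

#' Glance at a power-law fit
#'
#' @inheritParams tidy.powerlaw_fit
#' @return A one-row tibble with the fit constants, the one-sided slope
#'   p-value and the fit size.
#' @export
glance.powerlaw_fit <- function(x, ...) {
  y <- x$model$model[[1]]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(x$model$residuals^2) / tss else NA_real_
  tibble(D_inf = x$D_inf, c = x$c, c_prime = x$c_prime,
         p_slope = x$p_slope, r_squared = r2, n = x$n)
}

#' Generic tidiers
#'
#' Minimal broom-style generics for the package's fitted objects.
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Volume-weighted ensemble power-law parameters
#'
#' `D_inf = sum f_i D_inf_i` and `c = sum f_i c_i`: because the ensemble
#' diffusivity is the volume-weighted mean of the per-axon diffusivities,
#' its power-law constants are the same weighted means of the per-axon
#' constants (when all axons share the fit window).
#'
#' @param fits A list of `powerlaw_fit` objects (one per axon).
#' @param f Volume fractions summing to 1.
#' @return A one-row tibble with `D_inf` and `c`.
#' @export
ensemble_params <- function(fits, f) {
  stopifnot(length(fits) == length(f),
            all(vapply(fits, inherits, logical(1), "powerlaw_fit")))
  if (abs(sum(f) - 1) > 1e-8) {
    stop_axonwalk("volume fractions must sum to 1",
                  "axonwalk_error_fractions")
  }
  tibble(D_inf = sum(f * vapply(fits, `[[`, numeric(1), "D_inf")),
         c = sum(f * vapply(fits, `[[`, numeric(1), "c")))
}

#' Dispersion scaling of axial power-law parameters
#'
#' For an axially symmetric orientation dispersion with aggregate angle
#' `theta` (degrees, `theta = acos sqrt(<cos^2>)`), the bundle-axis
#' diffusivity, `D_inf` and `c` all scale by `<cos^2 theta> = cos^2(theta)`
#' relative to the aligned bundle.
#'
#' @param value Parameter value at `theta = 0`.
#' @param theta Aggregate dispersion angle in degrees, in
#'   `[0, 54.7356]` (the uniform-dispersion limit).
#' @return The predicted dispersed-bundle value.
#' @examples
#' dispersion_scaling(1.25, 30)  # ~0.94
#' @export
dispersion_scaling <- function(value, theta) {
  if (any(theta < 0 | theta > 54.7357)) {
    stop_axonwalk("theta must lie in [0, 54.7356] degrees",
                  "axonwalk_error_invalid_spec")
  }
  value * cos(theta * pi / 180)^2
}

#' Relative diffusivity reduction versus caliber variation
#'
#' Per axon, `zeta = (D0 - D_inf_i) / D_inf_i` measures how much the
#' restrictions depress the bulk axial diffusivity below the intrinsic
#' value `D0`; to lowest order in the caliber fluctuations,
#' `zeta` is proportional to `CV^2(r)`. Returns the per-axon table with the
#' least-squares line of `zeta` on `CV^2` and the Pearson correlation.
#'
#' @param D0 Intrinsic (unrestricted) diffusivity (um^2/ms), e.g.
#'   [mixture_D0()].
#' @param D_inf Per-axon bulk diffusivities (um^2/ms), positive.
#' @param cv_r Per-axon caliber coefficients of variation.
#' @return A tibble of class `zeta_result` with columns `D_inf`, `cv_r`,
#'   `cv2`, `zeta`, and attributes `slope`, `intercept`, `pearson_r`, `D0`.
#' @export
zeta_relation <- function(D0, D_inf, cv_r) {
  check_number(D0, "D0", lower = 1e-12)
  stopifnot(length(D_inf) == length(cv_r))
  if (any(D_inf <= 0)) {
    stop_axonwalk("D_inf must be positive", "axonwalk_error_invalid_spec")
  }
  zeta <- (D0 - D_inf) / D_inf
  cv2 <- cv_r^2
  if (length(unique(cv2)) < 2L || sd(cv2) == 0) {
    stop_axonwalk("degenerate CV spread; no regression possible",
                  "axonwalk_error_degenerate")
  }
  fit <- lm(zeta ~ cv2)
  out <- tibble(D_inf = D_inf, cv_r = cv_r, cv2 = cv2, zeta = zeta)
  structure(out, slope = unname(coef(fit)[2]),
            intercept = unname(coef(fit)[1]),
            pearson_r = cor(zeta, cv2), D0 = D0,
            class = c("zeta_result", class(out)))
}

#' Volume-weighted intrinsic diffusivity of the two-compartment axon
#'
#' `D0 = (1 - f_m) D_a + f_m D_m`: the mixture intrinsic diffusivity of
#' axoplasm and mitochondria. With the default compartment values
#' (D_a = 2, D_m = 0.13, f_m = 0.06) this is 1.89 um^2/ms.
#'
#' @param D_a,D_m Compartment intrinsic diffusivities (um^2/ms).
#' @param f_m Mitochondrial volume fraction in `[0, 1]`.
#' @return Mixture diffusivity (um^2/ms).
#' @examples
#' mixture_D0(2, 0.13, 0.06)
#' @export
mixture_D0 <- function(D_a, D_m, f_m) {
  if (any(f_m < 0 | f_m > 1)) {
    stop_axonwalk("f_m must lie in [0, 1]", "axonwalk_error_invalid_spec")
  }
  (1 - f_m) * D_a + f_m * D_m
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Wraps [stats::wilcox.test()] for paired samples: exact null distribution
#' for up to 15 non-zero pairs, normal approximation beyond. Zero
#' differences are dropped (standard signed-rank convention) and their
#' count reported. The smallest attainable p at n pairs is `2^-n`
#' (0.03125 at n = 5).
#'
#' @param a,b Paired observations.
#' @param alternative `"greater"` tests whether `a` tends to exceed `b`.
#' @return A one-row tibble with `statistic`, `p_value`, `n_pairs`,
#'   `n_zero_dropped`.
#' @export
wilcoxon_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop_axonwalk("all paired differences are zero",
                  "axonwalk_error_degenerate")
  }
  exact <- length(d) <= 15L
  ties <- anyDuplicated(abs(d)) > 0L
  if (exact && ties) {
    # wilcox.test has no exact distribution under tied ranks; enumerate the
    # 2^n sign assignments with midranks instead
    dd <- if (alternative == "less") -d else d
    rk <- rank(abs(dd))
    w_obs <- sum(rk[dd > 0])
    n <- length(dd)
    w_all <- vapply(0:(2^n - 1L), function(m) {
      sum(rk[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
    }, numeric(1))
    p <- mean(w_all >= w_obs - 1e-9)
    return(tibble(statistic = w_obs, p_value = p,
                  n_pairs = length(d), n_zero_dropped = n_zero))
  }
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = !exact)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         n_pairs = length(d), n_zero_dropped = n_zero)
}

#' One-sided test of a positive 1/sqrt(t) slope in D(t)
#'
#' Regresses `D` on `1/sqrt(t)` and returns the one-sided p-value of the
#' slope t-statistic against the null of no positive correlation; the
#' detection test for diffusivity time dependence.
#'
#' @param data A data frame with columns `t` (ms) and `D` (um^2/ms),
#'   at least 3 rows.
#' @return One-sided p-value.
#' @export
slope_correlation_test <- function(data) {
  stopifnot(all(c("t", "D") %in% names(data)))
  if (nrow(data) < 3L) {
    stop_axonwalk("need >= 3 points", "axonwalk_error_invalid_spec")
  }
  model <- lm(D ~ I(1 / sqrt(t)), data = data)
  tstat <- coef(model)[2] / sqrt(suppressWarnings(vcov(model))[2, 2])
  unname(pt(tstat, model$df.residual, lower.tail = FALSE))
}
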