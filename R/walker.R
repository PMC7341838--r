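#' Monte-Carlo simulation configuration
#'
#' @param n_walkers Number of random walkers.
#' @param sample_times Diffusion times at which displacement moments are
#'   recorded (ms). Default: 20 log-spaced points in `[1, 100]` ms. The
#'   actual recorded times are rounded to whole steps.
#' @param dt Step duration (ms). If `NULL` (default), chosen at run time so
#'   the step length in the fastest compartment is `step_frac * h`.
#' @param step_frac Step length as a fraction of the voxel size when `dt`
#'   is derived (default 0.5; must be `<= 1`).
#' @param t2_weighting Accumulate per-walker T2 weights
#'   `w = exp(-sum dt / T2(label))` and use them in the moments.
#' @param seed Integer seed for walker initialization and stepping.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_walkers = 10000, sample_times = lseq(1, 100, 20),
                       dt = NULL, step_frac = 0.5, t2_weighting = FALSE,
                       seed = 1L) {
  check_number(n_walkers, "n_walkers", lower = 1)
  stopifnot(is.numeric(sample_times), all(sample_times > 0))
  if (!is.null(dt)) check_number(dt, "dt", lower = 1e-12)
  check_number(step_frac, "step_frac", lower = 1e-6, upper = 1)
  structure(
    list(n_walkers = as.integer(n_walkers),
         sample_times = sort(unique(sample_times)), dt = dt,
         step_frac = step_frac, t2_weighting = isTRUE(t2_weighting),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Random-walk step length
#'
#' `sqrt(6 D dt)`: the fixed jump length of a walker in three dimensions
#' for intrinsic diffusivity `D` and step duration `dt`. For the reference
#' values D = 2 um^2/ms and dt = 2e-4 ms this is 0.049 um (axoplasm), and
#' 0.013 um for D = 0.13 um^2/ms (mitochondria).
#'
#' @param D Intrinsic diffusivity (um^2/ms), `>= 0`; vectorized.
#' @param dt Step duration (ms).
#' @return Step length (um).
#' @examples
#' step_length(2, 2e-4)
#' @export
step_length <- function(D, dt) {
  if (any(D < 0)) {
    stop_axonwalk("D must be >= 0", "axonwalk_error_invalid_spec")
  }
  check_number(dt, "dt", lower = 1e-300)
  sqrt(6 * D * dt)
}

#' Membrane permeation probability
#'
#' One-step transit rule for highly permeable membranes: a walker crossing
#' from a compartment with diffusivity `D_from` into one with `D_to` is
#' accepted with probability `min(1, sqrt(D_to / D_from))`; the rule makes
#' the equilibrium walker density uniform across the interface.
#'
#' @param D_from Diffusivity of the current compartment (um^2/ms), `> 0`.
#' @param D_to Diffusivity of the target compartment (um^2/ms).
#' @return Acceptance probability in `[0, 1]`; vectorized.
#' @examples
#' permeation_probability(2, 0.13)
#' @export
permeation_probability <- function(D_from, D_to) {
  if (any(D_from <= 0)) {
    stop_axonwalk("D_from must be > 0", "axonwalk_error_invalid_spec")
  }
  pmin(1, sqrt(D_to / D_from))
}

#' Seed walkers uniformly inside a substrate
#'
#' Rejection sampling in the bounding box: uniform candidate positions are
#' kept when their voxel is intracellular (label 1 or 2).
#'
#' @param vol A [labeled_volume()].
#' @param n Number of walkers (0 gives an empty matrix).
#' @param seed Integer seed.
#' @return An `n x 3` matrix of positions (um), columns `x`, `y`, `z`.
#' @export
init_walkers <- function(vol, n, seed) {
  stopifnot(inherits(vol, "labeled_volume"))
  n <- as.integer(n)
  if (n < 0L) stop_axonwalk("n must be >= 0", "axonwalk_error_invalid_spec")
  d <- dim(vol$labels)
  h <- vol$h
  if (!any(vol$labels != 0L)) {
    stop_axonwalk("volume has no interior", "axonwalk_error_invalid_volume")
  }
  out <- matrix(numeric(0), 0, 3)
  if (n > 0L) {
    out <- local_seed(seed, {
      acc <- matrix(numeric(0), 0, 3)
      fill <- sum(vol$labels != 0L) / prod(d)
      while (nrow(acc) < n) {
        m <- ceiling(1.5 * (n - nrow(acc)) / max(fill, 1e-6))
        cand <- cbind(stats::runif(m, 0, d[1] * h),
                      stats::runif(m, 0, d[2] * h),
                      stats::runif(m, 0, d[3] * h))
        idx <- cbind(pmin(d[1], floor(cand[, 1] / h) + 1L),
                     pmin(d[2], floor(cand[, 2] / h) + 1L),
                     pmin(d[3], floor(cand[, 3] / h) + 1L))
        keep <- vol$labels[idx] != 0L
        acc <- rbind(acc, cand[keep, , drop = FALSE])
      }
      acc[seq_len(n), , drop = FALSE]
    })
  }
  colnames(out) <- c("x", "y", "z")
  out
}

moment_cols2 <- c("xx", "xy", "xz", "yy", "yz", "zz")
moment_cols4 <- c("xxxx", "xxxy", "xxxz", "xxyy", "xxyz", "xxzz",
                  "xyyy", "xyyz", "xyzz", "xzzz",
                  "yyyy", "yyyz", "yyzz", "yzzz", "zzzz")

assemble_moment_record <- function(raw, times, cfg, dt) {
  w_sum <- raw[, 1]
  m2 <- sweep(raw[, 5:10, drop = FALSE], 1, w_sum, "/")
  m4 <- sweep(raw[, 11:25, drop = FALSE], 1, w_sum, "/")
  colnames(m2) <- paste0("m2_", moment_cols2)
  colnames(m4) <- paste0("m4_", moment_cols4)
  out <- dplyr::bind_cols(
    tibble(t = times, n_walkers = raw[, 2], weight_sum = w_sum,
           occ_axoplasm = raw[, 3], occ_mito = raw[, 4]),
    as_tibble(m2), as_tibble(m4)
  )
  structure(out, dt = dt, config = cfg,
            class = c("moment_record", class(out)))
}

#' Run a random walk inside a labeled substrate
#'
#' Continuous-space fixed-step-length Monte Carlo: per step an isotropic
#' random direction of length `sqrt(6 D dt)` for the walker's current
#' compartment; steps into the exterior are rejected (the walker stays),
#' steps across the axoplasm/mitochondrion interface are accepted with
#' [permeation_probability()]; the z boundaries are mirrored (reflective
#' copies) while the true displacement keeps accumulating. Weighted second
#' and fourth displacement moment tensors are recorded at each sample time.
#'
#' @param vol A [labeled_volume()].
#' @param props A [compartment_props()].
#' @param cfg A [sim_config()].
#' @return A tibble of class `moment_record` with one row per sampled time:
#'   `t` (ms), `n_walkers`, `weight_sum`, compartment occupancy counts, the
#'   6 independent second moments `m2_*` (um^2) and 15 fourth moments
#'   `m4_*` (um^4), all weighted means over walkers.
#' @export
run_walk <- function(vol, props, cfg) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(props, "compartment_props"),
            inherits(cfg, "sim_config"))
  h <- vol$h
  D_max <- max(props$D_a, props$D_m)
  dt <- cfg$dt %||% (cfg$step_frac * h)^2 / (6 * D_max)
  if (step_length(D_max, dt) > h + 1e-12) {
    stop_axonwalk(
      sprintf("step length %.3g um exceeds voxel size %.3g um; reduce dt",
              step_length(D_max, dt), h),
      "axonwalk_error_config"
    )
  }
  sample_steps <- sort(unique(pmax(1L, as.integer(round(cfg$sample_times / dt)))))
  n_steps <- max(sample_steps)
  init <- init_walkers(vol, cfg$n_walkers, cfg$seed)
  raw <- .walk_cpp(as.integer(vol$labels), dim(vol$labels), h,
                   c(0, props$D_a, props$D_m),
                   c(0, 1 / props$T2_a, 1 / props$T2_m),
                   cfg$t2_weighting, init, dt, n_steps, sample_steps,
                   as.double(cfg$seed %% 2^31), FALSE, 0)
  assemble_moment_record(raw, sample_steps * dt, cfg, dt)
}

#' Run a free-diffusion random walk (no geometry)
#'
#' Reference simulation of unrestricted Gaussian diffusion with the same
#' stepping rule; useful for calibration: the apparent diffusivity must
#' equal `D` and the kurtosis 0 at every time.
#'
#' @param D Intrinsic diffusivity (um^2/ms).
#' @param cfg A [sim_config()]; `cfg$dt` defaults to 0.01 ms here.
#' @return A `moment_record` tibble.
#' @export
run_walk_free <- function(D, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_number(D, "D", lower = 1e-12)
  dt <- cfg$dt %||% 0.01
  sample_steps <- sort(unique(pmax(1L, as.integer(round(cfg$sample_times / dt)))))
  n_steps <- max(sample_steps)
  init <- matrix(0, cfg$n_walkers, 3)
  raw <- .walk_cpp(integer(1), c(1L, 1L, 1L), 1, c(0, D, D), c(0, 0, 0),
                   FALSE, init, dt, n_steps, sample_steps,
                   as.double(cfg$seed %% 2^31), TRUE, D)
  assemble_moment_record(raw, sample_steps * dt, cfg, dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
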