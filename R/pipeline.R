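#' Run the full substrate-to-fit pipeline
#'
#' Drives the whole chain: generate beaded (optionally undulating) axons,
#' morphometry (restriction statistics and caliber power spectrum),
#' Monte-Carlo walk per axon, per-axon and ensemble cumulants along the
#' bundle axis, and the power-law fit of the ensemble D(t). Stage outputs
#' are written as CSV under `out_dir` together with a JSON run manifest
#' (config snapshot, seeds, file hashes, timings). Stages whose output
#' files already exist are reloaded instead of recomputed when
#' `resume = TRUE`.
#'
#' @param config A config list (see [default_config()] / [read_config()]).
#' @param seed Integer master seed; per-axon and per-stage seeds are
#'   derived from it deterministically.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage outputs.
#' @return A list with `profiles`, `morphometry`, `cumulants` (per-axon
#'   tibble), `ensemble` (D(t) tibble), `fit` (a `powerlaw_fit`) and
#'   `manifest`, invisibly; everything is also on disk under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = tempfile("axonwalk_run_"),
                         resume = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  sub <- config$substrate
  cmp <- config$compartments
  sim <- config$simulation
  spec <- bead_spec(sub$a_mean, sub$a_sd, sub$l_mean, sub$amplitude, sub$r0)
  props <- compartment_props(cmp$D_a, cmp$D_m, cmp$T2_a, cmp$T2_m, cmp$f_m)
  axon_seeds <- seed * 1000L + seq_len(sub$n_axons)

  # --- substrates -----------------------------------------------------
  stage_t <- Sys.time()
  profiles <- purrr::map(axon_seeds, function(s) {
    if (sub$scenario == "straight") {
      radius_profile(rep(sub$r0, round(sub$length / sub$dz)), sub$dz)
    } else {
      pos <- generate_restriction_positions(sub$length, spec, seed = s)
      generate_radius_profile(pos, spec, dz = sub$dz)
    }
  })
  profiles <- normalize_volumes(profiles)
  purrr::iwalk(profiles, function(p, i) {
    write_profile_csv(p, file.path(out_dir, sprintf("profile_%02d.csv", i)))
  })
  timings$substrate <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- morphometry ----------------------------------------------------
  stage_t <- Sys.time()
  concat <- concatenate_profiles(profiles, seed = seed)
  morpho <- if (sub$scenario == "straight") {
    tibble(a_mean = NA_real_, a_sd = NA_real_, l_est = NA_real_,
           plateau = NA_real_, p = NA_real_,
           cv_r = caliber_stats(concat)$cv_r)
  } else {
    rs <- find_restrictions(concat)
    # plateau estimation needs several spectrum points below 0.5/a; short
    # substrates may not provide them
    pl <- tryCatch(
      estimate_plateau_and_p(power_spectrum_density(concat),
                             a_mean = rs$a_mean),
      axonwalk_error = function(e) tibble(plateau = NA_real_, p = NA_real_)
    )
    tibble(a_mean = rs$a_mean, a_sd = rs$a_sd, l_est = rs$l_est,
           plateau = pl$plateau, p = pl$p,
           cv_r = caliber_stats(concat)$cv_r)
  }
  readr::write_csv(morpho, file.path(out_dir, "morphometry.csv"))
  timings$morphometry <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- simulation + cumulants ----------------------------------------
  stage_t <- Sys.time()
  cum_path <- file.path(out_dir, "cumulants.csv")
  vols <- vapply(profiles, profile_volume, numeric(1))
  fr <- vols / sum(vols)
  if (resume && file.exists(cum_path)) {
    axons <- readr::read_csv(cum_path, show_col_types = FALSE)
  } else {
    axons <- purrr::imap(profiles, function(p, i) {
      skel <- if (sub$scenario %in% c("I", "II")) {
        generate_skeleton(profile_length(p), sub$undulation_amplitude,
                          sub$undulation_wavelength, sub$dz,
                          seed = axon_seeds[i] + 1L)
      } else {
        NULL
      }
      vol <- make_scenario(p, sub$scenario, skeleton = skel, props = props,
                           h = sub$h, seed = axon_seeds[i] + 2L)
      cfg <- sim_config(
        n_walkers = sim$n_walkers,
        sample_times = lseq(sim$t_min, sim$t_max, sim$n_times),
        dt = sim$dt, step_frac = sim$step_frac,
        t2_weighting = sim$t2_weighting, seed = axon_seeds[i] + 3L
      )
      rec <- run_walk(vol, props, cfg)
      axon_cumulants(rec, c(0, 0, 1), f = fr[i], id = i)
    }) |>
      dplyr::bind_rows()
    readr::write_csv(axons, cum_path)
  }
  timings$simulation <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- ensemble + fit -------------------------------------------------
  stage_t <- Sys.time()
  ens <- dplyr::left_join(ensemble_D(axons), ensemble_K(axons), by = "t")
  readr::write_csv(ens, file.path(out_dir, "ensemble.csv"))
  fit <- fit_power_law(ens, window = config$fit$window)
  readr::write_csv(glance(fit), file.path(out_dir, "fit.csv"))
  timings$fit <- as.numeric(Sys.time() - stage_t, units = "secs")

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("axonwalk")),
    seed = seed, axon_seeds = axon_seeds, config = config,
    timings_sec = timings,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
    total_sec = as.numeric(Sys.time() - t0, units = "secs")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, morphometry = morpho,
                 cumulants = axons, ensemble = ens, fit = fit,
                 manifest = manifest, out_dir = out_dir))
}
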