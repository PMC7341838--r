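# Units are fixed package-wide at the I/O boundary: lengths in um, times in
# ms, diffusivities in um^2/ms, b-values in ms/um^2.

#' Read and write labeled substrate volumes as NIfTI
#'
#' Integer compartment labels with the isotropic voxel size carried in the
#' NIfTI pixdim header. The round trip preserves labels and voxel size
#' exactly.
#'
#' @param vol A [labeled_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a [labeled_volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  im <- RNifti::asNifti(vol$labels, datatype = "int16", internal = FALSE)
  im <- RNifti::asNifti(im, reference = list(
    pixdim = c(-1, vol$h, vol$h, vol$h, 1, 1, 1, 1)
  ))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  h <- RNifti::pixdim(im)[1]
  labeled_volume(array(as.integer(im), dim = dim(im)), h)
}

#' Read and write radius profiles as CSV
#'
#' Columns `z`, `r` (um) at full double precision; the grid spacing is
#' recovered from the z column on read.
#'
#' @param profile A [radius_profile()].
#' @param path File path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a [radius_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radius_profile"))
  readr::write_csv(tibble(z = profile$z, r = profile$r), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("z", "r") %in% names(df)))
  dz <- median(diff(df$z))
  radius_profile(df$r, dz)
}

#' Read a region-of-interest diffusivity-versus-time table
#'
#' Expects columns `subject`, `roi`, `t_ms`, `D` and optionally `K`;
#' returns a tibble with `t_ms` renamed to `t` so each
#' `(subject, roi)` group feeds [fit_power_law()] directly.
#'
#' @param path CSV file path.
#' @return A tibble with columns `subject`, `roi`, `t`, `D` (and `K`).
#' @export
read_roi_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject", "roi", "t_ms", "D")
  if (!all(need %in% names(df))) {
    stop_axonwalk(
      sprintf("ROI table must have columns %s", paste(need, collapse = ", ")),
      "axonwalk_error_schema"
    )
  }
  dplyr::rename(df, t = "t_ms")
}

config_schema <- list(
  substrate = c("n_axons", "length", "a_mean", "a_sd", "l_mean", "amplitude",
                "r0", "dz", "h", "undulation_amplitude",
                "undulation_wavelength", "scenario"),
  compartments = c("D_a", "D_m", "T2_a", "T2_m", "f_m"),
  simulation = c("n_walkers", "step_frac", "dt", "t_min", "t_max", "n_times",
                 "t2_weighting"),
  dispersion = c("kappa", "n_directions"),
  fit = c("window")
)

#' Default pipeline configuration
#'
#' The study conditions used throughout: restriction statistics
#' a = 5.70 um (SD 2.88 um), width 5.6 um, bead amplitude 0.3 on a 0.5 um
#' baseline radius; compartment values D_a = 2, D_m = 0.13 um^2/ms,
#' T2_a = 80, T2_m = 20 ms, f_m = 6%; voxel size 0.1 um; fit window
#' 20--80 ms.
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    substrate = list(n_axons = 4L, length = 60, a_mean = 5.70, a_sd = 2.88,
                     l_mean = 5.6, amplitude = 0.3, r0 = 0.5, dz = 0.1,
                     h = 0.1, undulation_amplitude = 0.5,
                     undulation_wavelength = 20, scenario = "II"),
    compartments = list(D_a = 2, D_m = 0.13, T2_a = 80, T2_m = 20,
                        f_m = 0.06),
    simulation = list(n_walkers = 2000L, step_frac = 0.5, t_min = 1,
                      t_max = 80, n_times = 16L, t2_weighting = FALSE),
    dispersion = list(kappa = Inf, n_directions = 0L),
    fit = list(window = c(20, 80))
  )
}

#' Read and validate a pipeline configuration file
#'
#' YAML with the sections and keys of [default_config()]; unknown sections
#' or keys are schema errors reported with their field path. Missing keys
#' fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_config
#' @param config A config list to validate/merge against the defaults.
#' @export
validate_config <- function(config) {
  base <- default_config()
  bad_sections <- setdiff(names(config), names(config_schema))
  if (length(bad_sections) > 0L) {
    stop_axonwalk(
      sprintf("unknown config section(s): %s",
              paste(bad_sections, collapse = ", ")),
      "axonwalk_error_schema"
    )
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(bad) > 0L) {
      stop_axonwalk(
        sprintf("unknown config key(s): %s",
                paste(paste0(sec, ".", bad), collapse = ", ")),
        "axonwalk_error_schema"
      )
    }
    base[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (is.character(base$dispersion$kappa)) {
    base$dispersion$kappa <- as.numeric(
      sub("^inf$", "Inf", base$dispersion$kappa, ignore.case = TRUE)
    )
  }
  base
}
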