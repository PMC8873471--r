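#' Imaging-system configuration
#'
#' Bundles the physical parameters of the inline holographic imaging system
#' and the simulation grids derived from them. All other modules take an
#' `optics_config` so that physical conversions (pixel pitches, wavenumbers,
#' slice counts) have a single source of truth.
#'
#' Lengths carry explicit unit suffixes in the field names. The vacuum
#' wavelength is in nm, the in-medium wavelength is `wavelength_nm /
#' medium_index`. Two axial samplings coexist: a fine step (nm) used by the
#' beam-propagation forward model, chosen near a quarter of the in-medium
#' wavelength so that multiple scattering is modeled accurately, and a coarse
#' step (um) used for holographic backpropagation and all learning, chosen
#' near the axial resolution of the system.
#'
#' @param wavelength_nm Vacuum illumination wavelength (nm).
#' @param medium_index Refractive index of the immersion medium.
#' @param numerical_aperture Objective NA; must satisfy
#'   `0 < NA < medium_index`.
#' @param magnification Total lateral magnification onto the sensor.
#' @param sensor_pixel_um Physical sensor pixel pitch (um).
#' @param lateral_extent_x_um,lateral_extent_y_um Lateral field of view (um).
#' @param axial_extent_um Imaged depth range (um).
#' @param fine_axial_step_nm Axial step of the fine simulation grid (nm).
#' @param backprop_axial_step_um Axial step of the reconstruction grid (um).
#' @param lateral_pixels_x,lateral_pixels_y Lateral grid size in pixels.
#'
#' @return An object of class `optics_config` (a named list).
#'
#' @details The default values describe a HeNe-illuminated (632.8 nm) inline
#' holographic microscope with a 20x / 0.4 NA objective and a 3.45 um sensor
#' pixel imaging a 176.64 x 176.64 x 500 um^3 volume of particles suspended
#' in water (n = 1.33): effective lateral pixel 172.5 nm, 1024 x 1024
#' lateral grid, 4222 fine axial slices at 118.4 nm, 100 reconstruction
#' slices at 5 um.
#'
#' @seealso [optics_mini_config()] for a small grid suitable for CPU tests,
#'   [grid_dimensions()], [effective_pixel()].
#' @export
optics_config <- function(wavelength_nm = 632.8,
                          medium_index = 1.33,
                          numerical_aperture = 0.4,
                          magnification = 20,
                          sensor_pixel_um = 3.45,
                          lateral_extent_x_um = 176.64,
                          lateral_extent_y_um = 176.64,
                          axial_extent_um = 500,
                          fine_axial_step_nm = 118.4,
                          backprop_axial_step_um = 5,
                          lateral_pixels_x = 1024,
                          lateral_pixels_y = 1024) {
  cfg <- structure(list(
    wavelength_nm = wavelength_nm,
    medium_index = medium_index,
    numerical_aperture = numerical_aperture,
    magnification = magnification,
    sensor_pixel_um = sensor_pixel_um,
    lateral_extent_x_um = lateral_extent_x_um,
    lateral_extent_y_um = lateral_extent_y_um,
    axial_extent_um = axial_extent_um,
    fine_axial_step_nm = fine_axial_step_nm,
    backprop_axial_step_um = backprop_axial_step_um,
    lateral_pixels_x = lateral_pixels_x,
    lateral_pixels_y = lateral_pixels_y
  ), class = "optics_config")
  validate_optics_config(cfg)
  cfg
}

#' Reduced-scale configuration for desk-scale runs
#'
#' Same optical constants as [optics_config()] but a 128 x 128 x 100 um
#' grid (effective pixel 0.5 um) so that simulation, backpropagation and
#' training complete quickly on one CPU. The fine axial step is the
#' quarter in-medium wavelength; the reconstruction step stays at 5 um
#' (20 slices over 100 um).
#'
#' @param ... Overrides forwarded to [optics_config()].
#' @return An `optics_config`.
#' @export
optics_mini_config <- function(...) {
  args <- list(
    wavelength_nm = 632.8,
    medium_index = 1.33,
    numerical_aperture = 0.4,
    magnification = 20,
    sensor_pixel_um = 10,
    lateral_extent_x_um = 64,
    lateral_extent_y_um = 64,
    axial_extent_um = 100,
    fine_axial_step_nm = 632.8 / (4 * 1.33),
    backprop_axial_step_um = 5,
    lateral_pixels_x = 128,
    lateral_pixels_y = 128
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(optics_config, args)
}

validate_optics_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num_pos <- c("wavelength_nm", "medium_index", "magnification",
               "sensor_pixel_um", "lateral_extent_x_um", "lateral_extent_y_um",
               "axial_extent_um", "fine_axial_step_nm", "backprop_axial_step_um",
               "lateral_pixels_x", "lateral_pixels_y")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid optics config: `", f, "` must be a positive finite number",
           call. = FALSE)
    }
  }
  na <- cfg$numerical_aperture
  if (!is.numeric(na) || length(na) != 1L || na <= 0 || na >= cfg$medium_index) {
    stop("invalid optics config: numerical aperture must satisfy 0 < NA < medium index",
         call. = FALSE)
  }
  # pixel-pitch consistency: sensor pixel demagnified onto the sample must
  # tile the stated lateral extent with the stated pixel count (0.1% slack)
  eff_um <- cfg$sensor_pixel_um / cfg$magnification
  grid_um <- cfg$lateral_extent_x_um / cfg$lateral_pixels_x
  if (abs(eff_um - grid_um) > 1e-3 * grid_um) {
    stop("invalid optics config: sensor_pixel/magnification (", signif(eff_um, 6),
         " um) does not match lateral_extent_x/lateral_pixels_x (",
         signif(grid_um, 6), " um)", call. = FALSE)
  }
  # the fine axial step must resolve the in-medium wavelength at ~lambda_m/4
  lambda_m_nm <- cfg$wavelength_nm / cfg$medium_index
  if (cfg$fine_axial_step_nm > lambda_m_nm / 4 * 1.01) {
    stop("invalid optics config: fine_axial_step_nm exceeds a quarter of the ",
         "in-medium wavelength (", signif(lambda_m_nm / 4, 6), " nm)",
         call. = FALSE)
  }
  if (cfg$fine_axial_step_nm / 1000 > cfg$axial_extent_um ||
      cfg$backprop_axial_step_um > cfg$axial_extent_um) {
    stop("invalid optics config: axial step exceeds axial extent", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.optics_config <- function(x, ...) {
  gd <- grid_dimensions(x)
  cat("<optics_config>\n")
  cat(sprintf("  lambda = %.1f nm (in medium %.2f nm), NA = %.2f, %gx magnification\n",
              x$wavelength_nm, x$wavelength_nm / x$medium_index,
              x$numerical_aperture, x$magnification))
  cat(sprintf("  effective pixel %.1f nm; volume %.2f x %.2f x %.1f um^3\n",
              effective_pixel(x), x$lateral_extent_x_um, x$lateral_extent_y_um,
              x$axial_extent_um))
  cat(sprintf("  grids: %d x %d x %d fine voxels, %d reconstruction slices at %.1f um\n",
              gd$nx, gd$ny, gd$n_fine_z, gd$n_coarse_z, x$backprop_axial_step_um))
  invisible(x)
}

#' Effective lateral pixel size at the sample (nm)
#'
#' The sensor pixel pitch demagnified by the imaging system,
#' `sensor_pixel / magnification`.
#'
#' @param config An [optics_config()].
#' @return Effective pixel size in nm.
#' @examples
#' effective_pixel(optics_config()) # 172.5 nm
#' @export
effective_pixel <- function(config) {
  validate_optics_config(config)
  config$sensor_pixel_um * 1000 / config$magnification
}

#' Lateral resolution of the system (um)
#'
#' Diffraction-limited lateral resolution `lambda_m / NA`, where `lambda_m`
#' is the in-medium wavelength.
#'
#' @param config An [optics_config()].
#' @return Lateral resolution in um (display-round to 0.1 um).
#' @examples
#' lateral_resolution(optics_config()) # ~1.2 um
#' @export
lateral_resolution <- function(config) {
  validate_optics_config(config)
  (config$wavelength_nm / config$medium_index / 1000) / config$numerical_aperture
}

#' Axial resolution of the system (um)
#'
#' `lambda_m / (1 - sqrt(1 - NA^2))`; the depth-of-focus-type axial
#' resolution of a coherent system with aperture NA.
#'
#' @param config An [optics_config()]; requires `NA < 1`.
#' @return Axial resolution in um.
#' @examples
#' axial_resolution(optics_config()) # ~5.7 um
#' @export
axial_resolution <- function(config) {
  validate_optics_config(config)
  na <- config$numerical_aperture
  if (na >= 1) stop("axial resolution undefined for NA >= 1", call. = FALSE)
  (config$wavelength_nm / config$medium_index / 1000) / (1 - sqrt(1 - na^2))
}

#' Grid dimensions implied by a configuration
#'
#' @param config An [optics_config()].
#' @return A list with `nx`, `ny` (lateral pixels), `n_fine_z` (fine
#'   simulation slices, floor of extent/step) and `n_coarse_z`
#'   (reconstruction slices, extent/step rounded).
#' @details The fine slice count uses floor (partial trailing slices are
#'   dropped); the coarse count uses round. With the default configuration
#'   this yields 1024 x 1024 x 4222 fine voxels and 100 coarse slices.
#' @examples
#' grid_dimensions(optics_config())
#' @export
grid_dimensions <- function(config) {
  validate_optics_config(config)
  eff_nm <- effective_pixel(config)
  list(
    nx = as.integer(round(config$lateral_extent_x_um * 1000 / eff_nm)),
    ny = as.integer(round(config$lateral_extent_y_um * 1000 / eff_nm)),
    n_fine_z = as.integer(floor(config$axial_extent_um * 1000 /
                                  config$fine_axial_step_nm)),
    n_coarse_z = as.integer(round(config$axial_extent_um /
                                    config$backprop_axial_step_um))
  )
}

#' In-medium wavelength in um
#' @param config An [optics_config()].
#' @return Wavelength in the medium, um.
#' @keywords internal
wavelength_medium_um <- function(config) {
  config$wavelength_nm / config$medium_index / 1000
}

#' Write / read an optics configuration as YAML
#'
#' Field names keep their unit suffixes so the file is self-describing.
#'
#' @param config An [optics_config()].
#' @param path File path.
#' @return `write_optics_config` returns `path` invisibly;
#'   `read_optics_config` returns an `optics_config`.
#' @export
write_optics_config <- function(config, path) {
  validate_optics_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_optics_config
#' @export
read_optics_config <- function(path) {
  do.call(optics_config, yaml::read_yaml(path))
}
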