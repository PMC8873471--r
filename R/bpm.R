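#' Angular-spectrum transfer kernel
#'
#' Frequency-domain transfer function for free-space propagation over
#' `distance_um` in the medium: `exp(i 2 pi z sqrt(1/lambda_m^2 - u^2 - v^2))`
#' on the propagating band, 0 on the evanescent band. Frequencies follow the
#' FFT layout for an `nx` x `ny` grid with pitch `pitch_um`.
#'
#' @param nx,ny Grid size in pixels.
#' @param pitch_um Lateral sampling pitch (um).
#' @param lambda_m_um In-medium wavelength (um).
#' @param distance_um Propagation distance (um); may be negative.
#' @return An `nx` x `ny` complex matrix in FFT frequency order.
#' @keywords internal
angular_spectrum_kernel <- function(nx, ny, pitch_um, lambda_m_um, distance_um) {
  u <- fft_freq(nx, pitch_um)
  v <- fft_freq(ny, pitch_um)
  arg <- outer(1 / lambda_m_um^2 - u^2, v^2, `-`)
  band <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  kern <- matrix(0 + 0i, nx, ny)
  kern[band] <- exp(2i * pi * distance_um * kz[band])
  kern
}

fft_freq <- function(n, pitch) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  k / (n * pitch)
}

#' Propagate a complex field by the angular-spectrum method
#'
#' Multiplies the field's 2D Fourier transform by the free-space transfer
#' kernel and transforms back. Evanescent components are zeroed, making the
#' operator exactly unitary on the propagating band; negative distances use
#' the conjugate kernel, so `propagate(z)` then `propagate(-z)` restores a
#' band-limited field.
#'
#' @param field Complex (or real) matrix matching the config's lateral grid.
#' @param distance_um Propagation distance in the medium (um), any sign.
#' @param config An [optics_config()].
#' @return Complex matrix of the propagated field.
#' @export
angular_spectrum_propagate <- function(field, distance_um, config) {
  validate_optics_config(config)
  gd <- grid_dimensions(config)
  if (!is.matrix(field) || nrow(field) != gd$nx || ncol(field) != gd$ny) {
    stop("field dimensions do not match the configured lateral grid", call. = FALSE)
  }
  pitch <- effective_pixel(config) / 1000
  kern <- angular_spectrum_kernel(gd$nx, gd$ny, pitch,
                                  wavelength_medium_um(config), distance_um)
  stats::fft(stats::fft(field) * kern, inverse = TRUE) / length(field)
}

#' Simulate an inline hologram by split-step beam propagation
#'
#' Propagates a unit-amplitude plane wave through the refractive-index
#' volume with the multiplicative split-step scheme: at each fine slice the
#' field acquires the thin phase screen
#' `exp(i (2 pi / lambda_vac) dn(x, y, z) dz_fine)` and is then diffracted
#' over `dz_fine` in the background medium by the angular-spectrum kernel.
#' This models the full multiple-scattering process (each slice re-scatters
#' the already-scattered field). The hologram plane is the exit face of the
#' volume; the recorded hologram is the exit intensity `|field|^2`.
#'
#' @param volume An `index_volume` from [voxelize()].
#' @param config An [optics_config()]; defaults to the volume's own.
#' @param noise_sd Standard deviation of optional additive Gaussian
#'   intensity noise (0 disables); negative intensities are clamped at 0.
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @param pad_factor Integer FFT padding factor guarding against lateral
#'   wrap-around. The padding margin is filled with the unscattered carrier
#'   wave (which propagates invariantly), so a scatter-free volume still
#'   yields unit intensity exactly. Default 2 for grids up to 256 px, else 1
#'   (periodic).
#' @param condition Optional named list of scene metadata (density, diameter,
#'   contrast) stored on the hologram.
#' @return A `hologram`: list with `intensity` (nx x ny nonnegative matrix),
#'   `provenance = "simulated"`, `condition`, `config`.
#' @export
simulate_hologram <- function(volume, config = volume$config, noise_sd = 0,
                              seed = 1L, pad_factor = NULL, condition = list()) {
  stopifnot(inherits(volume, "index_volume"))
  validate_optics_config(config)
  gd <- grid_dimensions(config)
  dm <- dim(volume$values)
  if (!identical(as.integer(dm), c(gd$nx, gd$ny, gd$n_fine_z))) {
    stop("index volume dimensions (", paste(dm, collapse = " x "),
         ") do not match the configured fine grid", call. = FALSE)
  }
  if (is.null(pad_factor)) pad_factor <- if (gd$nx <= 256) 2L else 1L
  pad_factor <- as.integer(pad_factor)
  stopifnot(pad_factor >= 1L)

  pitch <- effective_pixel(config) / 1000
  dz <- config$fine_axial_step_nm / 1000
  lambda_m <- wavelength_medium_um(config)
  k0_vac <- 2 * pi / (config$wavelength_nm / 1000)  # vacuum wavenumber, um^-1

  npx <- pad_factor * gd$nx
  npy <- pad_factor * gd$ny
  kern <- angular_spectrum_kernel(npx, npy, pitch, lambda_m, dz)
  ix <- seq_len(gd$nx)
  iy <- seq_len(gd$ny)

  field <- matrix(1 + 0i, gd$nx, gd$ny)
  carrier <- 1 + 0i  # unscattered plane wave amplitude in the pad margin
  step_phase <- exp(2i * pi * dz / lambda_m)  # DC component of the kernel
  for (j in seq_len(gd$n_fine_z)) {
    dn <- volume$values[, , j]
    if (any(dn != 0)) field <- field * exp(1i * k0_vac * dn * dz)
    if (pad_factor > 1L) {
      padded <- matrix(carrier, npx, npy)
      padded[ix, iy] <- field
      padded <- stats::fft(stats::fft(padded) * kern, inverse = TRUE) /
        (npx * npy)
      field <- padded[ix, iy]
    } else {
      field <- stats::fft(stats::fft(field) * kern, inverse = TRUE) /
        (npx * npy)
    }
    carrier <- carrier * step_phase
  }
  intensity <- Mod(field)^2
  if (noise_sd > 0) {
    set.seed(seed)
    intensity <- pmax(intensity + stats::rnorm(length(intensity), 0, noise_sd), 0)
    dim(intensity) <- c(gd$nx, gd$ny)
  }
  new_hologram(intensity, "simulated", condition, config)
}

new_hologram <- function(intensity, provenance, condition, config) {
  stopifnot(all(intensity >= 0))
  structure(list(intensity = intensity, provenance = provenance,
                 condition = condition, config = config), class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d, %s, mean intensity %.4g\n",
              nrow(x$intensity), ncol(x$intensity), x$provenance,
              mean(x$intensity)))
  invisible(x)
}

#' Write / read holograms as 32-bit float TIFF
#'
#' @param hologram A `hologram`.
#' @param path TIFF path.
#' @param config An [optics_config()] reattached on read.
#' @return `write_hologram_tiff` returns `path` invisibly;
#'   `read_hologram_tiff` returns a `hologram` with
#'   `provenance = "measured"` unless metadata says otherwise.
#' @export
write_hologram_tiff <- function(hologram, path) {
  stopifnot(inherits(hologram, "hologram"))
  scale <- max(hologram$intensity, 1e-12)
  tiff::writeTIFF(hologram$intensity / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, provenance = hologram$provenance,
                            condition = hologram$condition),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hologram_tiff
#' @export
read_hologram_tiff <- function(path, config) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  meta_path <- paste0(path, ".json")
  scale <- 1
  provenance <- "measured"
  condition <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
    if (!is.null(meta$provenance)) provenance <- meta$provenance
    if (!is.null(meta$condition)) condition <- meta$condition
  }
  new_hologram(pmax(img * scale, 0), provenance, condition, config)
}
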