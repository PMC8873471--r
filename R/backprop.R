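#' Backward transfer kernel of the free-space Green's function
#'
#' Angular-spectrum (Weyl) form of the Green's-function transfer kernel for
#' a depth `z_um` behind the hologram plane, conjugated for backward
#' propagation: `conj(exp(i 2 pi z sqrt(1/lambda_m^2 - u^2 - v^2)))` on the
#' propagating band and 0 outside. Exactly unit-modulus on the band, hence
#' alias-free; any constant prefactor of the Green's function is irrelevant
#' because downstream preprocessing standardizes mean and variance.
#'
#' @param z_um Depth into the volume from the hologram plane (um, >= 0).
#' @param config An [optics_config()].
#' @param nx,ny Grid size (defaults to the config's lateral grid).
#' @return Complex matrix in FFT frequency order.
#' @export
greens_transfer_kernel <- function(z_um, config, nx = NULL, ny = NULL) {
  validate_optics_config(config)
  if (z_um < 0) stop("depth must be nonnegative", call. = FALSE)
  gd <- grid_dimensions(config)
  if (is.null(nx)) nx <- gd$nx
  if (is.null(ny)) ny <- gd$ny
  Conj(angular_spectrum_kernel(nx, ny, effective_pixel(config) / 1000,
                               wavelength_medium_um(config), z_um))
}

#' Holographic backpropagation of an intensity hologram
#'
#' Numerically propagates the hologram backwards from the hologram plane
#' into the object volume slice by slice:
#' `R(x, y; z_j) = IFT( FT(I) * H(u, v; z_j) )` with `H` the backward
#' Green's-function transfer kernel. This is the minimum-norm linear
#' (first-Born) estimate of the 3D field; it is heavily contaminated by
#' scattering artifacts at high particle density, which is what the
#' descattering network removes.
#'
#' Slice depths are `j * backprop_axial_step` for `j = 1..n_coarse_z`
#' (shallowest slice nearest the hologram plane, which itself is not a
#' reconstruction slice), tiling `(0, axial_extent]`.
#'
#' @param hologram A `hologram` (or bare intensity matrix).
#' @param config An [optics_config()]; defaults to the hologram's own.
#' @return A `backprop_volume`: list with `values` (nx x ny x n_coarse_z
#'   complex array), `slice_depths_um`, `config`.
#' @export
backpropagate <- function(hologram, config = NULL) {
  if (inherits(hologram, "hologram")) {
    if (is.null(config)) config <- hologram$config
    intensity <- hologram$intensity
  } else {
    intensity <- hologram
  }
  if (is.null(config)) stop("an optics config is required", call. = FALSE)
  validate_optics_config(config)
  gd <- grid_dimensions(config)
  if (!is.matrix(intensity) || nrow(intensity) != gd$nx ||
      ncol(intensity) != gd$ny) {
    stop("hologram dimensions do not match the configured lateral grid",
         call. = FALSE)
  }
  pitch <- effective_pixel(config) / 1000
  lambda_m <- wavelength_medium_um(config)
  depths <- seq_len(gd$n_coarse_z) * config$backprop_axial_step_um
  spec <- stats::fft(intensity)
  vol <- array(0 + 0i, dim = c(gd$nx, gd$ny, gd$n_coarse_z))
  for (j in seq_along(depths)) {
    kern <- Conj(angular_spectrum_kernel(gd$nx, gd$ny, pitch, lambda_m,
                                         depths[j]))
    vol[, , j] <- stats::fft(spec * kern, inverse = TRUE) / length(intensity)
  }
  structure(list(values = vol, slice_depths_um = depths, config = config),
            class = "backprop_volume")
}

#' @export
print.backprop_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<backprop_volume> %d x %d x %d complex voxels, depths %.1f..%.1f um\n",
              d[1], d[2], d[3], min(x$slice_depths_um), max(x$slice_depths_um)))
  invisible(x)
}

#' Write / read a volume as a multi-page 32-bit TIFF stack
#'
#' Real 3D arrays are written as one page per axial slice; complex arrays as
#' two stacks (`<path>` with suffixes `_re.tif` / `_im.tif`). A JSON sidecar
#' records the value range used for scaling and the slice depths.
#'
#' @param values 3D numeric or complex array.
#' @param path Output path (complex input: a stem, `.tif` appended per part).
#' @param slice_depths_um Optional axial slice depths stored in the sidecar.
#' @return `write_volume_tiff` returns the path(s) invisibly;
#'   `read_volume_tiff` returns the array (complex when both parts exist).
#' @export
write_volume_tiff <- function(values, path, slice_depths_um = NULL) {
  if (is.complex(values)) {
    stem <- sub("\\.tiff?$", "", path)
    p1 <- write_volume_tiff(Re(values), paste0(stem, "_re.tif"), slice_depths_um)
    p2 <- write_volume_tiff(Im(values), paste0(stem, "_im.tif"), slice_depths_um)
    return(invisible(c(p1, p2)))
  }
  stopifnot(length(dim(values)) == 3L)
  lo <- min(values)
  hi <- max(values)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(values)[3]), function(j) (values[, , j] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = span,
                            slice_depths_um = slice_depths_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  stem <- sub("\\.tiff?$", "", path)
  re_path <- paste0(stem, "_re.tif")
  if (!file.exists(path) && file.exists(re_path)) {
    re <- read_volume_tiff(re_path)
    im <- read_volume_tiff(paste0(stem, "_im.tif"))
    return(complex(real = re, imaginary = im) |> array(dim = dim(re)))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (j in seq_along(pages)) {
    pg <- pages[[j]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[, , j] <- pg
  }
  arr * as.numeric(meta$scale) + as.numeric(meta$offset)
}
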