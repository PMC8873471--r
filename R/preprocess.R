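#' Standardize an array to zero mean and unit variance
#'
#' Applied to the amplitude of a backpropagated volume and to raw hologram
#' intensities before they enter the network. Normalization is always
#' computed on the whole volume or hologram, never per patch, so that patch
#' statistics retain the relative scattering level of the parent image.
#'
#' @param x Numeric array of any shape (a complex array is reduced to its
#'   amplitude first).
#' @return A list with `values` (same shape, mean 0, sd 1), `source_mean`,
#'   `source_sd`.
#' @export
normalize_array <- function(x) {
  if (is.complex(x)) x <- Mod(x)
  mu <- mean(x)
  sdev <- stats::sd(as.vector(x))
  if (!is.finite(sdev) || sdev == 0) {
    stop("cannot normalize a constant array (zero variance)", call. = FALSE)
  }
  list(values = (x - mu) / sdev, source_mean = mu, source_sd = sdev)
}

#' Lateral patch origins for a tiling with overlap
#'
#' Offsets start at 0 and advance by `stride`; a trailing remainder that
#' cannot hold a full patch is dropped (floor rule), giving
#' `floor((image_size - patch) / stride) + 1` origins per dimension. With a
#' 1024-px image, 128-px patches and stride 64 (64-px overlap) this yields
#' 15 origins per dimension, 225 patches per image; at stride 128 (no
#' overlap), 8 and 64.
#'
#' @param image_size Image size in pixels.
#' @param patch Patch size in pixels (must not exceed `image_size`).
#' @param stride Step between consecutive origins (>= 1).
#' @return Integer vector of 0-based offsets.
#' @export
patch_origins <- function(image_size, patch, stride) {
  stopifnot(stride >= 1)
  if (patch > image_size) {
    stop("patch size exceeds image size", call. = FALSE)
  }
  seq.int(0L, by = as.integer(stride),
          length.out = (image_size - patch) %/% stride + 1L)
}

#' Assemble paired training patches from co-registered volumes
#'
#' Each parent triple (amplitude volume, hologram, label volume) is
#' normalized as a whole, then cut into laterally co-registered
#' `patch x patch` tiles: an input sub-volume spanning all axial slices, the
#' matching hologram patch (the gating network's input), and the binary
#' label sub-volume. Training uses stride `patch/2` (half-patch overlap);
#' validation and testing use stride `patch` (no overlap).
#'
#' @param volumes List of complex or real 3D arrays (backpropagated volumes).
#' @param holograms List of matching intensity matrices (or `hologram`s).
#' @param labels List of matching binary 3D arrays (or `ground_truth_volume`s).
#' @param patch Lateral patch size in pixels (default 128).
#' @param role One of `"train"`, `"val"`, `"test"`; selects the stride.
#' @param stride Overrides the role-derived stride if given.
#' @return A `patch_dataset`: list of patch pairs, each with
#'   `input_subvolume`, `hologram_patch`, `label_subvolume`, `origin`
#'   (0-based `(x0, y0)`), `parent` (index of the source volume).
#' @export
build_dataset <- function(volumes, holograms, labels, patch = 128L,
                          role = c("train", "val", "test"), stride = NULL) {
  role <- match.arg(role)
  stopifnot(length(volumes) == length(holograms),
            length(volumes) == length(labels))
  if (is.null(stride)) stride <- if (role == "train") patch %/% 2L else patch
  pairs <- list()
  for (k in seq_along(volumes)) {
    vol <- volumes[[k]]
    if (inherits(vol, "backprop_volume")) vol <- vol$values
    holo <- holograms[[k]]
    if (inherits(holo, "hologram")) holo <- holo$intensity
    lab <- labels[[k]]
    if (inherits(lab, "ground_truth_volume")) lab <- lab$labels
    dv <- dim(vol)
    if (!identical(dim(lab), dv)) {
      stop("volume and label shapes differ for image ", k, call. = FALSE)
    }
    if (!identical(as.integer(dim(holo)), as.integer(dv[1:2]))) {
      stop("hologram and volume lateral shapes differ for image ", k,
           call. = FALSE)
    }
    nvol <- normalize_array(vol)$values
    nhol <- normalize_array(holo)$values
    ox <- patch_origins(dv[1], patch, stride)
    oy <- patch_origins(dv[2], patch, stride)
    for (y0 in oy) {
      for (x0 in ox) {
        xi <- (x0 + 1L):(x0 + patch)
        yi <- (y0 + 1L):(y0 + patch)
        pairs[[length(pairs) + 1L]] <- list(
          input_subvolume = nvol[xi, yi, , drop = FALSE],
          hologram_patch = nhol[xi, yi, drop = FALSE],
          label_subvolume = lab[xi, yi, , drop = FALSE],
          origin = c(x0, y0),
          parent = k
        )
      }
    }
  }
  structure(pairs, class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  if (length(x)) {
    d <- dim(x[[1]]$input_subvolume)
    cat(sprintf("<patch_dataset> %d pairs of %d x %d x %d sub-volumes\n",
                length(x), d[1], d[2], d[3]))
  } else {
    cat("<patch_dataset> empty\n")
  }
  invisible(x)
}
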