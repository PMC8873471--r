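#' Otsu threshold of a numeric vector
#'
#' 256-bin histogram over the data's own range; returns the bin boundary
#' maximizing the between-class variance.
#'
#' @param x Numeric values.
#' @param bins Histogram bins (default 256).
#' @return Threshold value; values strictly above it are foreground.
#' @export
otsu_threshold <- function(x, bins = 256L) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < 1e-12) return(hi)
  edges <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          bins), nbins = bins)
  p <- counts / sum(counts)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  edges[k + 1L]
}

#' Slice-wise Otsu binarization of a probability volume
#'
#' Each axial slice is thresholded independently with [otsu_threshold()]
#' (scattering artifacts grow with depth, so a global threshold would
#' over-segment shallow slices). Near-constant slices (range below `1e-6`)
#' are set entirely to background.
#'
#' @param prob_volume 3D array of per-voxel probabilities.
#' @return Integer 0/1 array of the same shape.
#' @export
binarize_volume <- function(prob_volume) {
  d <- dim(prob_volume)
  stopifnot(length(d) == 3L)
  out <- array(0L, dim = d)
  for (j in seq_len(d[3])) {
    sl <- prob_volume[, , j]
    if (max(sl) - min(sl) < 1e-6) next
    out[, , j] <- (sl > otsu_threshold(sl)) * 1L
  }
  out
}

#' Remove small connected components
#'
#' Components under 26-connectivity with fewer than `min_voxels` voxels are
#' discarded as noise (they are much smaller than the ~21-voxel footprint
#' of a 1 um particle on the reconstruction grid); components with
#' `min_voxels` or more are kept.
#'
#' @param binary_volume Integer/logical 3D array.
#' @param min_voxels Minimum size to keep (default 10).
#' @return Filtered integer 0/1 array.
#' @export
filter_clusters <- function(binary_volume, min_voxels = 10L) {
  labels <- label_components_cpp(as_binary_int(binary_volume))
  if (max(labels) == 0L) return(labels * 0L)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_voxels)
  out <- array(0L, dim = dim(labels))
  out[labels %in% keep] <- 1L
  out
}

as_binary_int <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  storage.mode(x) <- "integer"
  x
}

#' Centroids of connected components in physical units
#'
#' One centroid per 26-connected component: the mean of the member voxel
#' centers, converted to um with the effective lateral pixel and the
#' reconstruction slice spacing (slice `j` sits at depth `j * step`).
#'
#' @param binary_volume Filtered binary volume on the reconstruction grid.
#' @param config An [optics_config()].
#' @param source Provenance tag stored on the result (`"predicted"` or
#'   `"ground_truth"`).
#' @return A `centroid_set`: data.frame with `x_um`, `y_um`, `z_um`,
#'   `n_voxels`, plus attribute `source`.
#' @export
detect_centroids <- function(binary_volume, config, source = "predicted") {
  labels <- label_components_cpp(as_binary_int(binary_volume))
  n <- max(labels)
  pitch <- effective_pixel(config) / 1000
  dz <- config$backprop_axial_step_um
  if (n == 0L) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      n_voxels = integer(0))
    attr(out, "source") <- source
    class(out) <- c("centroid_set", class(out))
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  d <- dim(labels)
  i1 <- ((idx - 1L) %% d[1]) + 1L
  i2 <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  i3 <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  out <- data.frame(
    x_um = as.vector(tapply((i1 - 0.5) * pitch, lab, mean)),
    y_um = as.vector(tapply((i2 - 0.5) * pitch, lab, mean)),
    z_um = as.vector(tapply(i3 * dz, lab, mean)),
    n_voxels = as.vector(tapply(idx, lab, length))
  )
  attr(out, "source") <- source
  class(out) <- c("centroid_set", class(out))
  out
}

#' Centroid set from a particle table
#'
#' Ground-truth particle positions as a `centroid_set` for matching. The
#' axial coordinate is converted from the scene convention (distance from
#' the illumination entrance face) to the reconstruction convention
#' (depth behind the hologram plane, `Lz - z`), matching
#' [detect_centroids()] output.
#' @param field A `particle_field`.
#' @param config An [optics_config()] fixing the axial extent `Lz`.
#' @return A `centroid_set` with `source = "ground_truth"`.
#' @export
truth_centroids <- function(field, config) {
  out <- data.frame(x_um = field$particles$x_um, y_um = field$particles$y_um,
                    z_um = config$axial_extent_um - field$particles$z_um,
                    n_voxels = NA_integer_)
  attr(out, "source") <- "ground_truth"
  class(out) <- c("centroid_set", class(out))
  out
}

#' Match predicted to ground-truth particles and label TP/FP/FN
#'
#' Solves the minimum-total-Euclidean-distance one-to-one assignment
#' between predicted and ground-truth centroids (the smaller set is fully
#' matched; surplus members stay unmatched), then labels each matched pair
#' a true positive only if the prediction lies inside the elliptical
#' proximity volume of its ground-truth partner:
#' `(dx/a)^2 + (dy/a)^2 + (dz/c)^2 <= 1` with semi-axes `a = gate[1]/2`,
#' `c = gate[3]/2` (default gate 4 x 4 x 12 um, i.e. 4x the particle size
#' laterally and about twice the axial resolution in depth). Matched pairs
#' outside the gate contribute one FP and one FN; unmatched predictions are
#' FP, unmatched truths FN.
#'
#' @param predicted,truth `centroid_set`s (data.frames with `x_um`,
#'   `y_um`, `z_um`).
#' @param gate_um Ellipse dimensions (full axes) in um.
#' @param anisotropic_distance If `TRUE`, the assignment distance is
#'   normalized by the gate semi-axes instead of being isotropic (default
#'   `FALSE`: match on plain Euclidean distance, gate applied afterwards).
#' @return A `localization_report`: list with `counts` (tp, fp, fn),
#'   `predicted` and `truth` data.frames with a `label` column and matched
#'   partner index, and `pairs`.
#' @export
match_and_classify <- function(predicted, truth, gate_um = c(4, 4, 12),
                               anisotropic_distance = FALSE) {
  np <- nrow(predicted)
  nt <- nrow(truth)
  semi <- gate_um / 2
  pred_lab <- rep("FP", np)
  truth_lab <- rep("FN", nt)
  pred_match <- rep(NA_integer_, np)
  truth_match <- rep(NA_integer_, nt)
  pairs <- data.frame(predicted = integer(0), truth = integer(0),
                      distance_um = numeric(0), tp = logical(0))
  if (np > 0L && nt > 0L) {
    dx <- outer(predicted$x_um, truth$x_um, `-`)
    dy <- outer(predicted$y_um, truth$y_um, `-`)
    dz <- outer(predicted$z_um, truth$z_um, `-`)
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    cost <- if (anisotropic_distance) {
      sqrt((dx / semi[1])^2 + (dy / semi[2])^2 + (dz / semi[3])^2)
    } else {
      dist
    }
    if (np <= nt) {
      assign <- lap_cpp(cost)
      pi <- seq_len(np)
      ti <- assign
    } else {
      assign <- lap_cpp(t(cost))
      ti <- seq_len(nt)
      pi <- assign
    }
    inside <- (dx[cbind(pi, ti)] / semi[1])^2 + (dy[cbind(pi, ti)] / semi[2])^2 +
      (dz[cbind(pi, ti)] / semi[3])^2 <= 1
    pred_match[pi] <- ti
    truth_match[ti] <- pi
    pred_lab[pi[inside]] <- "TP"
    truth_lab[ti[inside]] <- "TP"
    pairs <- data.frame(predicted = pi, truth = ti,
                        distance_um = dist[cbind(pi, ti)], tp = inside)
  }
  pred_df <- cbind(as.data.frame(predicted), label = pred_lab,
                   matched_truth = pred_match)
  truth_df <- cbind(as.data.frame(truth), label = truth_lab,
                    matched_predicted = truth_match)
  counts <- c(tp = sum(pred_lab == "TP"), fp = sum(pred_lab == "FP"),
              fn = sum(truth_lab == "FN"))
  structure(list(counts = counts, predicted = pred_df, truth = truth_df,
                 pairs = pairs, gate_um = gate_um),
            class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  cat(sprintf("<localization_report> TP %d, FP %d, FN %d (JI %.3f)\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"],
              jaccard_index(x$counts["tp"], x$counts["fp"], x$counts["fn"])))
  invisible(x)
}

#' Jaccard index of a detection result
#'
#' `JI = TP / (TP + FP + FN)`; similarity between the predicted and true
#' particle sets. Undefined (returns `NA`) when all three counts are zero.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard_index <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  denom <- tp + fp + fn
  if (denom == 0) return(NA_real_)
  unname(tp / denom)
}

report_slice_bins <- function(report, config, bin_slices) {
  dz <- config$backprop_axial_step_um
  slice_of <- function(z) pmax(1L, as.integer(round(z / dz)))
  # TP and FN bins come from the ground-truth particle; FP bins from the
  # predicted particle (no truth partner exists)
  tp_fn_bins <- ceiling(slice_of(report$truth$z_um) / bin_slices)
  fp_sel <- report$predicted$label == "FP"
  fp_bins <- ceiling(slice_of(report$predicted$z_um[fp_sel]) / bin_slices)
  list(tp_bins = tp_fn_bins[report$truth$label == "TP"],
       fn_bins = tp_fn_bins[report$truth$label == "FN"],
       fp_bins = fp_bins)
}

#' Depth-binned Jaccard index curves
#'
#' The JI is computed per group of `bin_slices` axial slices (10 slices =
#' 50 um with the default 5 um spacing) for each volume; the summary is
#' the mean and standard deviation across volumes per bin. TP and FN
#' particles fall into the bin of their ground-truth depth, FP particles
#' into the bin of their predicted depth. Bins with no particles in a
#' volume are flagged `NA` for that volume and excluded from the summary.
#'
#' @param reports A `localization_report` or list of them (one per volume).
#' @param config An [optics_config()].
#' @param bin_slices Slices per depth bin (default 10).
#' @return A data.frame with `bin`, `depth_min_um`, `depth_max_um`,
#'   `mean_ji`, `sd_ji`, `n_volumes`.
#' @export
depthwise_ji <- function(reports, config, bin_slices = 10L) {
  if (inherits(reports, "localization_report")) reports <- list(reports)
  gd <- grid_dimensions(config)
  n_bins <- ceiling(gd$n_coarse_z / bin_slices)
  per_volume <- vapply(reports, function(rep) {
    b <- report_slice_bins(rep, config, bin_slices)
    vapply(seq_len(n_bins), function(k) {
      jaccard_index(sum(b$tp_bins == k), sum(b$fp_bins == k),
                    sum(b$fn_bins == k))
    }, numeric(1))
  }, numeric(n_bins))
  per_volume <- matrix(per_volume, nrow = n_bins)
  dz <- config$backprop_axial_step_um
  data.frame(
    bin = seq_len(n_bins),
    depth_min_um = (seq_len(n_bins) - 1L) * bin_slices * dz,
    depth_max_um = pmin(seq_len(n_bins) * bin_slices, gd$n_coarse_z) * dz,
    mean_ji = apply(per_volume, 1L, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }),
    sd_ji = apply(per_volume, 1L, function(v) {
      if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
    }),
    n_volumes = apply(per_volume, 1L, function(v) sum(!is.na(v)))
  )
}

#' Per-condition statistics of synthesis weights
#'
#' Component-wise mean and standard deviation of the gating weights for
#' each scattering condition; since every sample sums to one, the per-
#' condition means do too.
#'
#' @param alpha_samples Numeric matrix, one row per sample, one column per
#'   expert.
#' @param condition Factor/character vector of length `nrow(alpha_samples)`.
#' @return A data.frame with `condition`, `expert`, `mean`, `sd`, `n`.
#' @export
weight_statistics <- function(alpha_samples, condition) {
  alpha_samples <- as.matrix(alpha_samples)
  stopifnot(nrow(alpha_samples) == length(condition))
  if (nrow(alpha_samples) == 0L) stop("no synthesis-weight samples", call. = FALSE)
  if (any(abs(rowSums(alpha_samples) - 1) > 1e-6)) {
    stop("synthesis-weight samples must sum to 1", call. = FALSE)
  }
  condition <- as.factor(condition)
  if (any(table(condition) == 0L)) stop("empty condition group", call. = FALSE)
  out <- do.call(rbind, lapply(levels(condition), function(cc) {
    rows <- alpha_samples[condition == cc, , drop = FALSE]
    data.frame(condition = cc, expert = seq_len(ncol(rows)),
               mean = colMeans(rows),
               sd = apply(rows, 2L, stats::sd),
               n = nrow(rows))
  }))
  rownames(out) <- NULL
  out
}

#' Full localization scoring of a probability volume
#'
#' Binarize (slice-wise Otsu), filter sub-`min_voxels` clusters, detect
#' centroids, and match against the ground-truth particle table.
#'
#' @param prob_volume 3D probability array on the reconstruction grid.
#' @param field Ground-truth `particle_field`.
#' @param config An [optics_config()].
#' @param gate_um Proximity ellipse (um).
#' @param min_voxels Cluster-size filter.
#' @return A `localization_report`.
#' @export
evaluate_localization <- function(prob_volume, field, config,
                                  gate_um = c(4, 4, 12), min_voxels = 10L) {
  bin <- binarize_volume(prob_volume)
  bin <- filter_clusters(bin, min_voxels)
  pred <- detect_centroids(bin, config)
  match_and_classify(pred, truth_centroids(field, config), gate_um)
}

#' Serialize a localization report
#'
#' @param report A `localization_report`.
#' @param path Output path (`.json`); a depth-bin CSV is written when
#'   `config` is supplied.
#' @param config Optional [optics_config()] for the depth-binned curve.
#' @return `path`, invisibly.
#' @export
write_localization_report <- function(report, path, config = NULL) {
  payload <- list(counts = as.list(report$counts),
                  ji = jaccard_index(report$counts["tp"], report$counts["fp"],
                                     report$counts["fn"]),
                  gate_um = report$gate_um,
                  pairs = report$pairs,
                  predicted = report$predicted,
                  truth = report$truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(config)) {
    utils::write.csv(depthwise_ji(report, config),
                     sub("\\.json$", "_depth_ji.csv", path), row.names = FALSE)
  }
  invisible(path)
}
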