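# Shared fixtures: a small imaging geometry whose full simulate/backprop
# chain runs in under a second, toy patch datasets built from it, and
# brute-force oracles for assignment, labeling and thresholding. Generated
# objects are cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 64 x 64 px over 32 x 32 um laterally (0.5 um pixel), 40 um deep:
# 336 fine BPM slices, 8 reconstruction slices at 5 um.
toy_optics <- function() {
  optics_mini_config(lateral_extent_x_um = 32, lateral_extent_y_um = 32,
                     axial_extent_um = 40, lateral_pixels_x = 64,
                     lateral_pixels_y = 64)
}

toy_box <- function() c(32, 32, 40)

# Simulate n_particles 2-um spheres per seed, backpropagate, and cut into
# 32 x 32 x 8 patch pairs (4 non-overlapping tiles per volume).
toy_pairs <- function(n_particles, seeds) {
  cfg <- toy_optics()
  out <- list()
  for (s in seeds) {
    key <- sprintf("pairs_%d_%d", n_particles, s)
    out <- c(out, cached(key, {
      fld <- sample_particle_field(n_particles, toy_box(), seed = s,
                                   diameter_um = 2, index_contrast = 0.26,
                                   min_distance_um = 3)
      iv <- voxelize(fld, cfg)
      holo <- simulate_hologram(iv, cfg)
      bp <- backpropagate(holo, cfg)
      gt <- ground_truth_from_index_volume(iv)
      build_dataset(list(bp), list(holo), list(gt), patch = 32L, role = "val")
    }))
  }
  out
}

toy_spec <- function(n_experts = 2L) {
  dsn_mini_architecture(patch = c(32L, 32L, 8L), n_experts = n_experts,
                        n_scales = 2L, base_channels = 2L,
                        gtn_channels = c(4L, 8L), gtn_hidden = 8L)
}

# A tiny architecture whose forward/backward passes run in milliseconds.
micro_spec <- function(n_experts = 3L) {
  dsn_mini_architecture(patch = c(8L, 8L, 4L), n_experts = n_experts,
                        n_scales = 1L, base_channels = 2L,
                        gtn_channels = c(2L), gtn_hidden = 4L)
}

micro_sample <- function(spec, seed = 1L) {
  set.seed(seed)
  list(input_subvolume = array(rnorm(prod(spec$patch)), dim = spec$patch),
       hologram_patch = matrix(rnorm(prod(spec$patch[1:2])), spec$patch[1],
                               spec$patch[2]),
       label_subvolume = array(rbinom(prod(spec$patch), 1L, 0.3),
                               dim = spec$patch))
}

# GTN parameters that force a one-hot alpha on expert i regardless of input.
force_onehot <- function(params, i, n = length(params$experts)) {
  params$gtn$fc2$W[] <- 0
  params$gtn$fc2$b <- rep(-50, n)
  params$gtn$fc2$b[i] <- 50
  params
}

# Exhaustive minimum-cost injection of rows into columns (n <= m).
bf_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- acc
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Independent flood fill (26-connectivity) counting components and sizes.
flood_fill_components <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  sizes <- integer(0)
  neighbors <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  neighbors <- neighbors[rowSums(abs(neighbors)) > 0, ]
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) for (k0 in seq_len(d[3])) {
    if (!mask[i0, j0, k0] || visited[i0, j0, k0]) next
    queue <- matrix(c(i0, j0, k0), ncol = 3)
    visited[i0, j0, k0] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (r in seq_len(nrow(neighbors))) {
        p <- cur + neighbors[r, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && !visited[p[1], p[2], p[3]]) {
          visited[p[1], p[2], p[3]] <- TRUE
          queue <- rbind(queue, p)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Exhaustive Otsu: evaluate the between-class variance at every one of the
# 256 histogram-bin boundaries and return the best boundary.
bf_otsu <- function(x, bins = 256L) {
  lo <- min(x)
  hi <- max(x)
  edges <- seq(lo, hi, length.out = bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  vals <- x * 0  # placeholder
  best_k <- NA_integer_
  best_v <- -Inf
  for (k in seq_len(bins)) {
    g0 <- bin <= k
    if (!any(g0) || all(g0)) next
    w0 <- mean(g0)
    mu0 <- mean(centers[bin[g0]])
    mu1 <- mean(centers[bin[!g0]])
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v) {
      best_v <- v
      best_k <- k
    }
  }
  edges[best_k + 1L]
}
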