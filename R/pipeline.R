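#' Enumerate scattering-condition grids
#'
#' Expands the named condition groups used for training and generalization
#' testing into a flat table: the four seen densities, the unseen-density
#' sweep, unseen diameters and index contrasts, joint size/contrast
#' combinations, a density sweep at unseen size and contrast, and the
#' three heterogeneity sweeps (uniformly distributed per-particle contrast
#' and/or diameter around central values). Densities are in 1e4 particles
#' per uL; heterogeneity half-widths in percent of the central value.
#'
#' @param groups Which condition groups to expand (default: all).
#' @return A data.frame with columns `group`, `density_e4_uL`,
#'   `diameter_um`, `dn`, `delta_n_pct`, `delta_D_pct`, `n_volumes`.
#' @export
make_condition_grid <- function(groups = c("seen_densities",
                                           "unseen_densities",
                                           "unseen_diameters",
                                           "unseen_contrasts",
                                           "size_contrast",
                                           "density_size_contrast",
                                           "contrast_heterogeneity",
                                           "size_heterogeneity",
                                           "joint_heterogeneity")) {
  if (is.null(groups) || !length(groups)) {
    return(data.frame(group = character(0), density_e4_uL = numeric(0),
                      diameter_um = numeric(0), dn = numeric(0),
                      delta_n_pct = numeric(0), delta_D_pct = numeric(0),
                      n_volumes = integer(0)))
  }
  groups <- match.arg(groups, several.ok = TRUE)
  cond <- function(group, density, diameter, dn, dnp = 0, ddp = 0, n = 10L) {
    data.frame(group = group, density_e4_uL = density, diameter_um = diameter,
               dn = dn, delta_n_pct = dnp, delta_D_pct = ddp, n_volumes = n)
  }
  parts <- list()
  if ("seen_densities" %in% groups) {
    parts$seen <- cond("seen_densities", c(1.6, 3.2, 6.41, 12.82), 1.0, 0.26)
  }
  if ("unseen_densities" %in% groups) {
    parts$ud <- cond("unseen_densities", c(2.24, 4.81, 9.61, 19.23, 25.64),
                     1.0, 0.26)
  }
  if ("unseen_diameters" %in% groups) {
    parts$usz <- cond("unseen_diameters", 6.41, c(0.30, 0.60, 1.40, 1.80), 0.26)
  }
  if ("unseen_contrasts" %in% groups) {
    parts$uct <- cond("unseen_contrasts", 6.41, 1.0,
                      c(0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50))
  }
  if ("size_contrast" %in% groups) {
    combos <- expand.grid(diameter_um = c(0.30, 0.60, 1.30, 1.50),
                          dn = c(0.10, 0.50))
    parts$sc <- cond("size_contrast", 6.41, combos$diameter_um, combos$dn)
  }
  if ("density_size_contrast" %in% groups) {
    parts$dsc <- cond("density_size_contrast",
                      c(2.24, 4.81, 9.61, 19.23, 25.64), 0.60, 0.10)
  }
  if ("contrast_heterogeneity" %in% groups) {
    parts$hn <- cond("contrast_heterogeneity", 6.41, 1.0, 0.20,
                     dnp = c(5, 12.5, 25, 50))
  }
  if ("size_heterogeneity" %in% groups) {
    parts$hd <- cond("size_heterogeneity", 6.41, 1.0, 0.20,
                     ddp = c(9, 17.5, 26, 34.5))
  }
  if ("joint_heterogeneity" %in% groups) {
    dnp <- c(5, 12.5, 25, 50)
    ddp <- c(9, 17.5, 26, 34.5)
    parts$hj <- cond("joint_heterogeneity", 6.41, 1.0, 0.20, dnp = dnp,
                     ddp = ddp)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Configuration for a pipeline run
#'
#' @param optics An [optics_config()] (default: the mini grid).
#' @param arch A [dsn_architecture()] whose axial patch equals the
#'   reconstruction slice count.
#' @param n_particles Particles per simulated volume.
#' @param diameter_um,dn Particle diameter and index contrast.
#' @param train A [train_config()].
#' @param seed Base seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(optics = optics_mini_config(axial_extent_um = 80),
                            arch = NULL, n_particles = 8L, diameter_um = 2.0,
                            dn = 0.26, train = train_config(max_iterations = 60L),
                            seed = 1L) {
  gd <- grid_dimensions(optics)
  if (is.null(arch)) {
    arch <- dsn_mini_architecture(patch = c(32L, 32L, gd$n_coarse_z))
  }
  if (arch$patch[3] != gd$n_coarse_z) {
    stop("architecture axial patch must equal the reconstruction slice count",
         call. = FALSE)
  }
  structure(list(optics = optics, arch = arch, n_particles = n_particles,
                 diameter_um = diameter_um, dn = dn, train = train,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

manifest_path <- function(run_dir) file.path(run_dir, "manifest.json")

read_manifest <- function(run_dir) {
  p <- manifest_path(run_dir)
  if (file.exists(p)) jsonlite::read_json(p) else
    list(version = as.character(utils::packageVersion("holodsn")),
         stages = list())
}

record_stage <- function(run_dir, stage, files, extra = list()) {
  man <- read_manifest(run_dir)
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  man$stages[[stage]] <- c(list(files = sums), extra)
  jsonlite::write_json(man, manifest_path(run_dir), auto_unbox = TRUE,
                       digits = NA)
  invisible(man)
}

#' Validate a run manifest against its artifacts
#'
#' @param run_dir Run directory.
#' @return `TRUE` invisibly; errors on a missing file or checksum mismatch.
#' @export
validate_manifest <- function(run_dir) {
  man <- read_manifest(run_dir)
  for (stage in names(man$stages)) {
    for (f in names(man$stages[[stage]]$files)) {
      path <- file.path(run_dir, f)
      if (!file.exists(path)) {
        stop("manifest lists missing artifact ", f, " (stage ", stage, ")",
             call. = FALSE)
      }
      have <- unname(tools::md5sum(path))
      want <- man$stages[[stage]]$files[[f]]
      if (!identical(have, want)) {
        stop("checksum mismatch for ", f, " (stage ", stage, ")", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

require_stage <- function(run_dir, file, needed_by, produced_by) {
  path <- file.path(run_dir, file)
  if (!file.exists(path)) {
    stop("stage '", needed_by, "' needs ", file, "; run stage '", produced_by,
         "' first", call. = FALSE)
  }
  path
}

#' Run one stage of the simulate-to-evaluate pipeline
#'
#' Stages: `"simulate"` (particle field, ground truth, BPM hologram),
#' `"backprop"` (complex reconstruction volume), `"dataset"` (normalized
#' patch pairs), `"train"` (expert or DSN checkpoint), `"infer"`
#' (descattered probability volume re-tiled from patches), `"evaluate"`
#' (localization report), `"weights_stats"` (gating-weight summary).
#' Deterministic stages re-run with the same config and seed reproduce
#' identical artifact checksums. Artifacts and their md5 sums accumulate in
#' `manifest.json` in the run directory.
#'
#' @param stage Stage name.
#' @param run_dir Artifact directory (created if needed).
#' @param config A [pipeline_config()].
#' @param model `"expert"` or `"dsn"` (train/infer/weights_stats stages).
#' @return Stage-dependent artifact list, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "backprop", "dataset", "train",
                                "infer", "evaluate", "weights_stats"),
                      run_dir, config = pipeline_config(), model = "dsn") {
  stage <- match.arg(stage)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  optics <- config$optics
  switch(stage,
    simulate = {
      box <- c(optics$lateral_extent_x_um, optics$lateral_extent_y_um,
               optics$axial_extent_um)
      field <- sample_particle_field(config$n_particles, box,
                                     seed = config$seed,
                                     diameter_um = config$diameter_um,
                                     index_contrast = config$dn)
      vol <- voxelize(field, optics)
      holo <- simulate_hologram(vol, optics,
                                condition = list(n = config$n_particles,
                                                 D = config$diameter_um,
                                                 dn = config$dn))
      pf <- file.path(run_dir, "particles.csv")
      hf <- file.path(run_dir, "hologram.tif")
      write_particle_csv(field, pf)
      write_hologram_tiff(holo, hf)
      record_stage(run_dir, "simulate", c(pf, hf),
                   list(seed = config$seed, n_particles = config$n_particles))
      invisible(list(field = field, hologram = holo))
    },
    backprop = {
      hf <- require_stage(run_dir, "hologram.tif", "backprop", "simulate")
      holo <- read_hologram_tiff(hf, optics)
      bp <- backpropagate(holo, optics)
      vf <- file.path(run_dir, "backprop")
      paths <- write_volume_tiff(bp$values, paste0(vf, ".tif"),
                                 bp$slice_depths_um)
      record_stage(run_dir, "backprop", paths)
      invisible(list(backprop = bp))
    },
    dataset = {
      require_stage(run_dir, "backprop_re.tif", "dataset", "backprop")
      pf <- require_stage(run_dir, "particles.csv", "dataset", "simulate")
      hf <- require_stage(run_dir, "hologram.tif", "dataset", "simulate")
      bp <- read_volume_tiff(file.path(run_dir, "backprop.tif"))
      field <- read_particle_csv(pf)
      holo <- read_hologram_tiff(hf, optics)
      gt <- make_ground_truth(field, optics)
      ds <- build_dataset(list(bp), list(holo), list(gt),
                          patch = config$arch$patch[1], role = "train")
      df <- file.path(run_dir, "dataset.rds")
      saveRDS(ds, df)
      record_stage(run_dir, "dataset", df, list(n_pairs = length(ds)))
      invisible(list(dataset = ds))
    },
    train = {
      df <- require_stage(run_dir, "dataset.rds", "train", "dataset")
      ds <- readRDS(df)
      fit <- train_model(if (model == "dsn") "dsn" else "expert", ds,
                         config$train, config$arch)
      cf <- file.path(run_dir, paste0(model, "_checkpoint.rds"))
      hf <- file.path(run_dir, paste0(model, "_history.csv"))
      save_checkpoint(fit$best_params, config$arch, cf)
      utils::write.csv(fit$history, hf, row.names = FALSE)
      record_stage(run_dir, "train", c(cf, hf), list(model = model))
      invisible(fit)
    },
    infer = {
      cf <- require_stage(run_dir, paste0(model, "_checkpoint.rds"), "infer",
                          "train")
      df <- require_stage(run_dir, "dataset.rds", "infer", "dataset")
      ck <- load_checkpoint(cf)
      ds <- readRDS(df)
      gd <- grid_dimensions(optics)
      prob <- array(0, dim = c(gd$nx, gd$ny, gd$n_coarse_z))
      patch <- ck$spec$patch[1]
      for (pair in ds) {
        if (any(pair$origin %% patch != 0L)) next  # non-overlapping tiles only
        fw <- if (model == "dsn") {
          dsn_forward(pair$input_subvolume, pair$hologram_patch, ck$params,
                      ck$spec)
        } else {
          expert_forward(pair$input_subvolume, ck$params, ck$spec)
        }
        xi <- pair$origin[1] + seq_len(patch)
        yi <- pair$origin[2] + seq_len(patch)
        prob[xi, yi, ] <- fw$prob
      }
      pf <- file.path(run_dir, "prediction.tif")
      write_volume_tiff(prob, pf)
      record_stage(run_dir, "infer", pf)
      invisible(list(prob = prob))
    },
    evaluate = {
      pf <- require_stage(run_dir, "prediction.tif", "evaluate", "infer")
      cf <- require_stage(run_dir, "particles.csv", "evaluate", "simulate")
      prob <- read_volume_tiff(pf)
      field <- read_particle_csv(cf)
      report <- evaluate_localization(prob, field, optics)
      rf <- file.path(run_dir, "localization_report.json")
      write_localization_report(report, rf, optics)
      record_stage(run_dir, "evaluate", rf,
                   list(counts = as.list(report$counts)))
      invisible(report)
    },
    weights_stats = {
      cf <- require_stage(run_dir, "dsn_checkpoint.rds", "weights_stats",
                          "train")
      df <- require_stage(run_dir, "dataset.rds", "weights_stats", "dataset")
      ck <- load_checkpoint(cf)
      ds <- readRDS(df)
      alphas <- t(vapply(ds, function(pair) {
        gtn_forward(pair$hologram_patch, ck$params$gtn, ck$spec)$alpha
      }, numeric(ck$spec$n_experts)))
      stats <- weight_statistics(alphas, rep("run", nrow(alphas)))
      sf <- file.path(run_dir, "weight_stats.csv")
      utils::write.csv(stats, sf, row.names = FALSE)
      record_stage(run_dir, "weights_stats", sf)
      invisible(stats)
    }
  )
}
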