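test_that("Otsu thresholding matches the exhaustive boundary search", {
  # bimodal slice: threshold falls strictly between the modes
  x <- c(rep(0.1, 900), rep(0.9, 100))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  set.seed(12)
  for (trial in 1:5) {
    y <- stats::runif(400)^sample(1:3, 1)
    expect_equal(otsu_threshold(y), bf_otsu(y), tolerance = 1e-12)
  }
})

test_that("binarization is slice-wise and zeroes near-constant slices", {
  vol <- array(0.2, dim = c(8, 8, 3))
  vol[2:3, 2:3, 2] <- 0.9
  vol[, , 3] <- 0.5  # constant slice
  bin <- binarize_volume(vol)
  expect_true(all(bin[, , 1] == 0))
  expect_true(all(bin[, , 3] == 0))
  expect_identical(sum(bin[, , 2]), 4L)
  expect_identical(which(bin[, , 2] == 1L), which(vol[, , 2] > 0.5))
})

test_that("cluster filtering discards below 10 voxels and keeps 10", {
  mk <- function(n) {
    v <- array(0L, dim = c(10, 10, 5))
    v[seq_len(n) + 10 * 2] <- 1L  # n voxels in a row: one 26-connected blob
    v
  }
  expect_identical(sum(filter_clusters(mk(9))), 0L)
  expect_identical(sum(filter_clusters(mk(10))), 10L)
})

test_that("connected-component counts agree with an independent flood fill", {
  set.seed(33)
  vol <- array(rbinom(12 * 12 * 6, 1L, 0.12), dim = c(12, 12, 6))
  sizes <- flood_fill_components(vol == 1L)
  labels <- holodsn:::label_components_cpp(vol)
  expect_identical(max(labels), length(sizes))
  expect_identical(sort(tabulate(labels[labels > 0])), sort(sizes))
  for (m in c(2L, 5L)) {
    expect_identical(sum(filter_clusters(vol, m)), sum(sizes[sizes >= m]))
  }
})

test_that("centroids are per-component voxel-center means in um", {
  cfg <- toy_optics()  # 0.5 um pixel, 5 um slices
  vol <- array(0L, dim = c(64, 64, 8))
  vol[3:4, 5:6, 2] <- 1L  # 2x2x1 block
  cs <- detect_centroids(vol, cfg)
  expect_identical(nrow(cs), 1L)
  expect_equal(cs$x_um, mean(c(2.5, 3.5)) * 0.5)  # voxel centers 1.25, 1.75
  expect_equal(cs$y_um, mean(c(4.5, 5.5)) * 0.5)
  expect_equal(cs$z_um, 10)

  expect_identical(nrow(detect_centroids(array(0L, c(4, 4, 2)), cfg)), 0L)

  vol[20:22, 30, 5] <- 1L
  cs2 <- detect_centroids(vol, cfg)
  expect_identical(nrow(cs2), 2L)
  second <- cs2[order(cs2$z_um), ][2, ]
  expect_equal(second$x_um, mean(c(19.5, 20.5, 21.5)) * 0.5)
  expect_equal(second$z_um, 25)
})

test_that("matching labels particles through the elliptical gate", {
  pts <- data.frame(x_um = c(5, 20, 28), y_um = c(5, 12, 3),
                    z_um = c(10, 25, 35))
  same <- match_and_classify(pts, pts)
  expect_identical(unname(same$counts), c(3L, 0L, 0L))

  # a 12.5-um axial displacement falls outside the 12-um (full-axis) gate
  off <- data.frame(x_um = 5, y_um = 5, z_um = 22.5)
  tru <- data.frame(x_um = 5, y_um = 5, z_um = 10)
  rep <- match_and_classify(off, tru)
  expect_identical(unname(rep$counts), c(0L, 1L, 1L))
  # ...but 5 um axial is inside (semi-axis 6 um)
  near <- data.frame(x_um = 5, y_um = 5, z_um = 15)
  expect_identical(unname(match_and_classify(near, tru)$counts), c(1L, 0L, 0L))
})

test_that("the assignment is the exhaustive minimum-cost injection (n <= 6)", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    pred <- data.frame(x_um = runif(n, 0, 30), y_um = runif(n, 0, 30),
                       z_um = runif(n, 0, 50))
    tru <- data.frame(x_um = runif(m, 0, 30), y_um = runif(m, 0, 30),
                      z_um = runif(m, 0, 50))
    rep <- match_and_classify(pred, tru, gate_um = c(1e6, 1e6, 1e6))
    cost <- sqrt(outer(pred$x_um, tru$x_um, `-`)^2 +
                 outer(pred$y_um, tru$y_um, `-`)^2 +
                 outer(pred$z_um, tru$z_um, `-`)^2)
    oracle <- if (n <= m) bf_assignment_cost(cost) else
      bf_assignment_cost(t(cost))
    expect_equal(sum(rep$pairs$distance_um), oracle, tolerance = 1e-9)
  }
})

test_that("TP/FP/FN conserve the set sizes and shrinkage is monotone", {
  set.seed(43)
  pred <- data.frame(x_um = runif(15, 0, 30), y_um = runif(15, 0, 30),
                     z_um = runif(15, 0, 40))
  tru <- data.frame(x_um = runif(12, 0, 30), y_um = runif(12, 0, 30),
                    z_um = runif(12, 0, 40))
  scales <- c(4, 2, 1, 0.5)
  tps <- vapply(scales, function(s) {
    rep <- match_and_classify(pred, tru, gate_um = s * c(4, 4, 12))
    expect_identical(unname(rep$counts["tp"] + rep$counts["fn"]), 12L)
    expect_identical(unname(rep$counts["tp"] + rep$counts["fp"]), 15L)
    unname(rep$counts["tp"])
  }, integer(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("the Jaccard index is TP over the union of labels", {
  expect_equal(jaccard_index(10, 0, 0), 1.0)
  expect_equal(jaccard_index(8, 1, 1), 0.8)
  expect_equal(jaccard_index(0, 3, 5), 0.0)
  expect_true(is.na(jaccard_index(0, 0, 0)))
  expect_error(jaccard_index(-1, 0, 0))
})

test_that("depth-binned curves aggregate per 10 slices across volumes", {
  cfg <- optics_mini_config()  # 20 slices of 5 um -> 2 bins of 10 slices
  mk_report <- function(pred, tru) match_and_classify(pred, tru)
  # all particles in bin 1: bin 1 carries the global JI, bin 2 is flagged
  pred <- data.frame(x_um = c(5, 10), y_um = c(5, 10), z_um = c(10, 20))
  tru <- data.frame(x_um = c(5, 10, 15), y_um = c(5, 10, 15),
                    z_um = c(10, 20, 30))
  curve <- depthwise_ji(mk_report(pred, tru), cfg)
  expect_identical(nrow(curve), 2L)
  expect_equal(curve$mean_ji[1], 2 / 3)
  expect_true(is.na(curve$mean_ji[2]))
  # two identical volumes: zero spread
  curve2 <- depthwise_ji(list(mk_report(pred, tru), mk_report(pred, tru)), cfg)
  expect_equal(curve2$sd_ji[1], 0)
  expect_identical(curve2$n_volumes[1], 2L)
  # hand-computed two-bin case: bin 1 has 1 TP; bin 2 has 1 TP, 1 FN, 1 FP
  predB <- data.frame(x_um = c(5, 10, 30), y_um = c(5, 10, 30),
                      z_um = c(10, 60, 75))
  truB <- data.frame(x_um = c(5, 10, 20), y_um = c(5, 10, 20),
                     z_um = c(10, 60, 80))
  curveB <- depthwise_ji(mk_report(predB, truB), cfg)
  expect_equal(curveB$mean_ji, c(1, 1 / 3))
})

test_that("synthesis-weight statistics summarize per condition", {
  a <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 1, 0))
  st <- weight_statistics(a, c("x", "x", "x", "x"))
  expect_equal(st$mean, c(0.5, 0.5, 0))
  expect_equal(sum(st$mean), 1, tolerance = 1e-6)

  same <- weight_statistics(rbind(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)),
                            c("a", "a"))
  expect_true(all(same$sd == 0))

  two <- weight_statistics(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)),
                           c("lo", "hi", "lo"))
  for (cc in c("lo", "hi")) {
    expect_equal(sum(two$mean[two$condition == cc]), 1, tolerance = 1e-6)
  }
  expect_error(weight_statistics(matrix(numeric(0), 0, 3), character(0)),
               "samples")
  expect_error(weight_statistics(rbind(c(0.5, 0.2)), "a"), "sum to 1")
})

test_that("a clean ground-truth volume scores a perfect Jaccard index", {
  cfg <- toy_optics()
  fld <- sample_particle_field(5, toy_box(), seed = 4, diameter_um = 3,
                               index_contrast = 0.26, min_distance_um = 8)
  gt <- make_ground_truth(fld, cfg)
  # footprints must be comfortably above the 10-voxel filter
  prob <- gt$labels * 0.9 + 0.05
  rep <- evaluate_localization(prob, fld, cfg)
  expect_identical(unname(rep$counts), c(5L, 0L, 0L))
  expect_equal(jaccard_index(rep$counts["tp"], rep$counts["fp"],
                             rep$counts["fn"]), 1.0)
})

test_that("localization reports serialize to JSON with a depth-bin CSV", {
  cfg <- toy_optics()
  pred <- data.frame(x_um = c(5, 10), y_um = c(5, 10), z_um = c(10, 20))
  rep <- match_and_classify(pred, pred)
  path <- tempfile(fileext = ".json")
  write_localization_report(rep, path, cfg)
  back <- jsonlite::read_json(path)
  expect_equal(back$counts$tp, 2)
  expect_equal(back$ji, 1)
  expect_true(file.exists(sub("\\.json$", "_depth_ji.csv", path)))
})
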