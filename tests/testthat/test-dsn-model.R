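test_that("gating weights are a softmax: positive, summing to one", {
  spec <- micro_spec()
  params <- init_parameters(spec, "dsn", seed = 2)
  set.seed(5)
  for (trial in 1:10) {
    h <- matrix(rnorm(64), 8, 8)
    a <- gtn_forward(h, params$gtn, spec)$alpha
    expect_lt(abs(sum(a) - 1), 1e-6)
    expect_true(all(a > 0 & a < 1))
  }
  # zeroed final layer -> uniform weights
  params$gtn$fc2$W[] <- 0
  params$gtn$fc2$b[] <- 0
  a <- gtn_forward(matrix(rnorm(64), 8, 8), params$gtn, spec)$alpha
  expect_equal(a, rep(1 / 3, 3))
  # determinism
  h <- matrix(rnorm(64), 8, 8)
  expect_identical(gtn_forward(h, params$gtn, spec)$alpha,
                   gtn_forward(h, params$gtn, spec)$alpha)
  expect_error(gtn_forward(matrix(0, 4, 4), params$gtn, spec), "patch")
})

test_that("the full-scale encoder bottleneck is 8 x 8 x 7", {
  spec <- dsn_architecture()
  expect_identical(bottleneck_shape(spec), c(8L, 8L, 7L))
  # run an actual (channel-thin) encoder at the full patch size
  thin <- dsn_architecture(base_channels = 1L)
  enc <- expert_encode(array(0, c(128, 128, 100)),
                       init_parameters(thin, "expert", 1)$encoder, thin)
  expect_identical(dim(enc$features$bottleneck)[1:3], c(8L, 8L, 7L))
  # mini preset arithmetic
  mini <- toy_spec()
  enc2 <- expert_encode(array(0, c(32, 32, 8)),
                        init_parameters(mini, "expert", 1)$encoder, mini)
  expect_identical(dim(enc2$features$bottleneck)[1:3], bottleneck_shape(mini))
  expect_error(expert_encode(array(0, c(16, 16, 8)),
                             init_parameters(mini, "expert", 1)$encoder, mini),
               "does not match")
})

test_that("zero inputs through zeroed convolutions give zero features", {
  spec <- micro_spec()
  params <- init_parameters(spec, "expert", seed = 3)
  zeroed <- params
  zeroed$encoder <- holodsn:::ptree_map(function(x) x * 0, params$encoder)
  # restore unit gains so instance norm is a pure pass-through of zeros
  for (s in seq_along(zeroed$encoder$scales)) {
    zeroed$encoder$scales[[s]]$conv1$gamma[] <- 1
    zeroed$encoder$scales[[s]]$conv2$gamma[] <- 1
  }
  zeroed$encoder$bottleneck$conv1$gamma[] <- 1
  zeroed$encoder$bottleneck$conv2$gamma[] <- 1
  enc <- expert_encode(array(0, spec$patch), zeroed$encoder, spec)
  expect_true(all(enc$features$bottleneck == 0))
  expect_true(all(vapply(enc$features$skips, function(f) all(f == 0),
                         logical(1))))
})

test_that("feature synthesis is the exact convex combination", {
  spec <- micro_spec()
  pyramids <- lapply(1:3, function(i) {
    expert_encode(micro_sample(spec, i)$input_subvolume,
                  init_parameters(spec, "expert", i)$encoder, spec)$features
  })
  # one-hot recovers a single pyramid exactly
  onehot <- synthesize_features(pyramids, c(0, 1, 0))
  expect_identical(onehot$bottleneck, pyramids[[2]]$bottleneck)
  expect_identical(onehot$skips, pyramids[[2]]$skips)
  # identical pyramids are a fixed point for any valid alpha
  same <- synthesize_features(list(pyramids[[1]], pyramids[[1]],
                                   pyramids[[1]]), c(0.2, 0.3, 0.5))
  expect_equal(same$bottleneck, pyramids[[1]]$bottleneck, tolerance = 1e-12)
  # scalar-loop oracle on the bottleneck
  alpha <- c(0.2, 0.3, 0.5)
  syn <- synthesize_features(pyramids, alpha)
  oracle <- array(0, dim = dim(pyramids[[1]]$bottleneck))
  for (idx in seq_along(oracle)) {
    for (i in 1:3) {
      oracle[idx] <- oracle[idx] + alpha[i] * pyramids[[i]]$bottleneck[idx]
    }
  }
  expect_equal(syn$bottleneck, oracle, tolerance = 1e-12)
  # incompatible shapes are rejected
  bad <- pyramids
  bad[[2]]$bottleneck <- bad[[2]]$bottleneck[, , 1, , drop = FALSE]
  expect_error(synthesize_features(bad, alpha), "compatible")
})

test_that("decoder synthesis mixes every learnable parameter linearly", {
  spec <- micro_spec()
  decs <- lapply(1:3, function(i) init_parameters(spec, "expert", i)$decoder)
  onehot <- synthesize_decoder(decs, c(0, 0, 1))
  expect_equal(onehot, holodsn:::ptree_map(function(x) 1 * x, decs[[3]]),
               tolerance = 1e-15)
  same <- synthesize_decoder(list(decs[[1]], decs[[1]], decs[[1]]),
                             c(0.25, 0.5, 0.25))
  expect_equal(same, holodsn:::ptree_map(function(x) 1 * x, decs[[1]]),
               tolerance = 1e-12)
  # two-expert toy with scalar parameters
  a <- list(head = list(w = array(2, c(1, 1, 1, 1, 1)), b = 4))
  b <- list(head = list(w = array(6, c(1, 1, 1, 1, 1)), b = 8))
  mix <- synthesize_decoder(list(a, b), c(0.25, 0.75))
  expect_equal(as.vector(mix$head$w), 0.25 * 2 + 0.75 * 6)
  expect_equal(mix$head$b, 0.25 * 4 + 0.75 * 8)
  # mismatched key sets are rejected
  broken <- decs
  names(broken[[2]]$head) <- c("w", "bias")
  expect_error(synthesize_decoder(broken, c(1, 0, 0) / 1), "key sets")
})

test_that("one-hot gating makes the DSN equal the selected expert", {
  spec <- micro_spec()
  params <- init_parameters(spec, "dsn", seed = 7)
  smp <- micro_sample(spec, 11)
  for (i in seq_len(spec$n_experts)) {
    forced <- force_onehot(params, i)
    dsn <- dsn_forward(smp$input_subvolume, smp$hologram_patch, forced, spec)
    solo <- expert_forward(smp$input_subvolume, params$experts[[i]], spec)
    rel <- max(abs(dsn$prob - solo$prob) / (abs(solo$prob) + 1e-12))
    expect_lt(rel, 1e-5)
  }
})

test_that("DSN output is a probability volume of the input shape", {
  spec <- micro_spec()
  params <- init_parameters(spec, "dsn", seed = 9)
  smp <- micro_sample(spec, 3)
  fw <- dsn_forward(smp$input_subvolume, smp$hologram_patch, params, spec)
  expect_identical(dim(fw$prob), dim(smp$input_subvolume))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # deterministic given parameters
  fw2 <- dsn_forward(smp$input_subvolume, smp$hologram_patch, params, spec)
  expect_identical(fw$prob, fw2$prob)
})

test_that("the synthesized decoder depends linearly on alpha", {
  spec <- micro_spec()
  decs <- lapply(1:3, function(i) init_parameters(spec, "expert", i)$decoder)
  a1 <- c(0.6, 0.3, 0.1)
  a2 <- c(0.1, 0.2, 0.7)
  lam <- 0.37
  mid <- synthesize_decoder(decs, lam * a1 + (1 - lam) * a2)
  d1 <- synthesize_decoder(decs, a1)
  d2 <- synthesize_decoder(decs, a2)
  combo <- holodsn:::ptree_map(function(x, y) lam * x + (1 - lam) * y, d1, d2)
  expect_equal(mid, combo, tolerance = 1e-12)
})

test_that("parameter counts scale as the architecture dictates", {
  spec <- dsn_architecture()
  ratio <- count_parameters(spec, "dsn") / count_parameters(spec, "expert")
  expect_gte(ratio, 2.9)
  expect_lte(ratio, 3.3)
  # doubling the width roughly quadruples the conv-dominated count
  narrow <- dsn_architecture(base_channels = 16L)
  wide <- dsn_architecture(base_channels = 32L)
  growth <- count_parameters(wide, "expert") / count_parameters(narrow, "expert")
  expect_gt(growth, 3.5)
  expect_lt(growth, 4.2)
  # the wide generalist matches the DSN's budget
  wg <- architecture_preset("wide_generalist")
  expect_equal(count_parameters(wg, "expert") / count_parameters(spec, "dsn"),
               1, tolerance = 0.1)
})
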