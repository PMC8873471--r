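test_that("binary cross entropy matches hand-computed values", {
  expect_equal(bce_loss(array(0.5, c(2, 3)), array(c(0, 1), c(2, 3))), log(2))
  expect_equal(bce_loss(c(0.8, 0.3), c(1, 0)),
               -0.5 * (log(0.8) + log(0.7)), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.8, 0.3), c(1, 0)), 0.2899, tolerance = 1e-4)
  # perfect prediction bottoms out at the clamping floor
  y <- c(0, 1, 1, 0)
  expect_lt(bce_loss(y, y), 2e-7)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("L2 regularization adds gamma times the squared parameter norm", {
  expect_identical(regularized_loss(1.5, list(a = 3), 0), 1.5)
  expect_equal(regularized_loss(1, list(w = 2), 0.5), 3)
  params <- list(a = c(1, 2), b = list(c = matrix(3, 1, 2)))
  expect_equal(regularized_loss(0, params, 1e-6), 1e-6 * (1 + 4 + 9 + 9))
})

test_that("analytic gradients match finite differences (with weight decay)", {
  spec <- micro_spec(n_experts = 2L)
  params <- init_parameters(spec, "expert", seed = 13)
  smp <- micro_sample(spec, 4)
  gamma <- 1e-3
  loss_of <- function(p) {
    fw <- expert_forward(smp$input_subvolume, p, spec)
    regularized_loss(bce_loss(fw$prob, smp$label_subvolume), p, gamma)
  }
  fw <- expert_forward(smp$input_subvolume, params, spec, with_cache = TRUE)
  glog <- (fw$prob - smp$label_subvolume) / length(fw$prob)
  dim(glog) <- dim(fw$logits)
  g <- expert_backward(fw$cache, params, glog, spec)
  # the regularized gradient is the data gradient plus 2 gamma w
  g <- holodsn:::ptree_map(function(gg, w) gg + 2 * gamma * w, g, params)
  leaves_p <- holodsn:::flatten_leaves(params)
  leaves_g <- holodsn:::flatten_leaves(g)
  set.seed(21)
  for (trial in 1:12) {
    j <- sample(length(leaves_p), 1)
    k <- sample(length(leaves_p[[j]]), 1)
    eps <- 1e-5
    bump <- function(delta) {
      ll <- leaves_p
      ll[[j]][k] <- ll[[j]][k] + delta
      holodsn:::unflatten_leaves(params, ll)
    }
    fd <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    an <- leaves_g[[j]][k]
    expect_equal(an, fd, tolerance = 1e-3)
  }
})

test_that("Xavier initialization has the prescribed variance", {
  # a large conv layer: fan_in = 27 * 64, fan_out = 27 * 64
  spec <- dsn_architecture(base_channels = 64L, n_scales = 1L,
                           patch = c(8L, 8L, 4L))
  params <- init_parameters(spec, "expert", seed = 31)
  w <- params$encoder$scales[[1]]$conv2$w  # 64 -> 64, 110k weights
  target <- 2 / (27 * 64 + 27 * 64)
  expect_lt(abs(var(as.vector(w)) - target) / target, 0.2)
  expect_true(all(params$encoder$scales[[1]]$conv2$b == 0))
  expect_true(all(params$encoder$scales[[1]]$conv2$gamma == 1))
  # deterministic under a fixed seed
  again <- init_parameters(spec, "expert", seed = 31)
  expect_identical(params, again)
})

test_that("initialization schemes place pretrained experts verbatim", {
  spec <- micro_spec(n_experts = 2L)
  ckpt <- lapply(1:2, function(i) init_parameters(spec, "expert", 100 + i))
  dsn <- initialize_model(spec, "dsn", scheme = "pretrained_experts",
                          pretrained = ckpt, seed = 1)
  expect_identical(dsn$experts, ckpt)
  expect_error(initialize_model(spec, "dsn", scheme = "pretrained_experts"),
               "checkpoint")
})

test_that("zero iterations return the initial parameters unchanged", {
  spec <- micro_spec(n_experts = 2L)
  ds <- list(micro_sample(spec, 1))
  init <- init_parameters(spec, "expert", seed = 5)
  fit <- train_model("expert", ds, train_config(max_iterations = 0L, seed = 5),
                     spec, params = init)
  expect_identical(fit$params, init)
  expect_identical(nrow(fit$history), 0L)
  expect_error(train_model("expert", list(), train_config(), spec), "empty")
})

test_that("training reduces the loss on a separable toy task", {
  spec <- dsn_mini_architecture(patch = c(16L, 16L, 8L), n_experts = 2L,
                                n_scales = 2L, base_channels = 4L,
                                gtn_channels = c(4L), gtn_hidden = 4L)
  # two far-apart bright blobs vs background: the input is the (noisy)
  # label pattern, so the mapping is separable
  set.seed(8)
  mk <- function() {
    lab <- array(0L, dim = spec$patch)
    lab[3:5, 3:5, 3:5] <- 1L
    lab[11:13, 11:13, 4:6] <- 1L
    list(input_subvolume = lab + array(rnorm(prod(spec$patch), 0, 0.1),
                                       dim = spec$patch),
         hologram_patch = matrix(rnorm(256), 16, 16),
         label_subvolume = lab)
  }
  ds <- replicate(4, mk(), simplify = FALSE)
  fit <- train_model("expert", ds,
                     train_config(learning_rate = 1e-3, max_iterations = 500L,
                                  seed = 9), spec)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  pred <- expert_forward(ds[[1]]$input_subvolume, fit$params, spec)$prob
  acc <- mean((pred > 0.5) == (ds[[1]]$label_subvolume == 1L))
  expect_gt(acc, 0.99)
})

test_that("a fixed seed reproduces the loss history exactly", {
  spec <- micro_spec(n_experts = 2L)
  ds <- lapply(1:3, function(i) micro_sample(spec, i))
  cfg <- train_config(learning_rate = 1e-3, max_iterations = 10L, seed = 17)
  h1 <- train_model("dsn", ds, cfg, spec)$history
  h2 <- train_model("dsn", ds, cfg, spec)$history
  expect_identical(h1, h2)
})

test_that("validation selects the lowest-validation-loss checkpoint", {
  spec <- micro_spec(n_experts = 2L)
  ds <- lapply(1:3, function(i) micro_sample(spec, i))
  val <- list(micro_sample(spec, 50))
  fit <- train_model("expert", ds,
                     train_config(learning_rate = 1e-3, max_iterations = 20L,
                                  seed = 3, validation_interval = 5L),
                     spec, validation = val)
  val_losses <- fit$history$val_loss[!is.na(fit$history$val_loss)]
  best <- mean(vapply(val, function(s) {
    bce_loss(expert_forward(s$input_subvolume, fit$best_params, spec)$prob,
             s$label_subvolume)
  }, numeric(1)))
  expect_equal(best, min(val_losses), tolerance = 1e-12)
})

test_that("checkpoints round-trip with their architecture", {
  spec <- micro_spec(n_experts = 2L)
  params <- init_parameters(spec, "expert", seed = 77)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, spec, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, params)
  expect_identical(back$spec, spec)
})

test_that("training presets carry the published hyperparameters", {
  expect_equal(train_preset("expert")$learning_rate, 1e-4)
  expect_identical(train_preset("expert")$batch_size, 4L)
  expect_equal(train_preset("generalist")$learning_rate, 1e-5)
  expect_identical(train_preset("generalist")$batch_size, 20L)
  dsn <- train_preset("dsn")
  expect_equal(dsn$learning_rate, 1e-5)
  expect_identical(dsn$batch_size, 1L)
  expect_equal(dsn$l2_gamma, 1e-6)
  expect_identical(dsn$init_scheme, "pretrained_experts")
})
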