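#' Binary cross-entropy over a probability volume
#'
#' `-(1/N) sum( y log p + (1 - y) log(1 - p) )` with `N` the number of
#' voxels in the batch. Predictions are clamped to `[eps, 1 - eps]`
#' (`eps = 1e-7`) for numerical safety. This detection loss weighs the
#' prediction error equally at all depths.
#'
#' @param pred Predicted probabilities, any array shape.
#' @param target Binary labels of the same shape.
#' @param eps Clamping floor.
#' @return Scalar loss.
#' @examples
#' bce_loss(array(0.5, c(2, 2)), array(c(0, 1, 0, 1), c(2, 2))) # log(2)
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  p <- pmin(pmax(as.vector(pred), eps), 1 - eps)
  y <- as.vector(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Add L2 weight decay to a loss value
#'
#' `loss + gamma * sum(w^2)` over every learnable parameter.
#'
#' @param loss Scalar data loss.
#' @param params Parameter tree (or flat numeric vector).
#' @param gamma Regularization strength (>= 0); 1e-6 in the DSN preset.
#' @return Scalar regularized loss.
#' @export
regularized_loss <- function(loss, params, gamma) {
  stopifnot(gamma >= 0)
  if (gamma == 0) return(loss)
  sq <- sum(vapply(flatten_leaves(params), function(w) sum(w^2), numeric(1)))
  loss + gamma * sq
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size Samples per gradient step.
#' @param max_iterations Gradient steps to run.
#' @param l2_gamma L2 weight-decay strength.
#' @param init_scheme `"xavier_all"` or `"pretrained_experts"` (DSN only).
#' @param seed RNG seed for initialization and sampling order.
#' @param validation_interval Iterations between validation-loss evaluations.
#' @return A `train_config` list.
#' @details `train_preset()` returns the hyperparameters used at full scale
#'   for each model family: expert (lr 1e-4, batch 4), generalist (lr 1e-5,
#'   batch 20), wide generalist (lr 1e-4, batch 1), DSN (lr 1e-5, batch 1,
#'   gamma 1e-6, experts initialized from pretrained checkpoints).
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1L,
                         max_iterations = 100L, l2_gamma = 0,
                         init_scheme = c("xavier_all", "pretrained_experts"),
                         seed = 1L, validation_interval = 50L) {
  stopifnot(learning_rate > 0, l2_gamma >= 0, batch_size >= 1L,
            max_iterations >= 0L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 l2_gamma = l2_gamma,
                 init_scheme = match.arg(init_scheme),
                 seed = as.integer(seed),
                 validation_interval = as.integer(validation_interval)),
            class = "train_config")
}

#' @rdname train_config
#' @param model Model family.
#' @param ... Overrides forwarded to [train_config()].
#' @export
train_preset <- function(model = c("expert", "generalist", "wide_generalist",
                                   "dsn"), ...) {
  model <- match.arg(model)
  base <- switch(model,
    expert = list(learning_rate = 1e-4, batch_size = 4L),
    generalist = list(learning_rate = 1e-5, batch_size = 20L),
    wide_generalist = list(learning_rate = 1e-4, batch_size = 1L),
    dsn = list(learning_rate = 1e-5, batch_size = 1L, l2_gamma = 1e-6,
               init_scheme = "pretrained_experts")
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(train_config, base)
}

#' Initialize model parameters
#'
#' The GTN is always Xavier-initialized. Experts are either copied from
#' pretrained per-density checkpoints (`"pretrained_experts"`; the full-
#' scale recipe pretrains on the three highest seen densities) or Xavier-
#' initialized (`"xavier_all"`).
#'
#' @param spec A [dsn_architecture()].
#' @param part `"expert"` or `"dsn"`.
#' @param scheme Initialization scheme.
#' @param pretrained List of expert parameter trees (length `n_experts`),
#'   required for `"pretrained_experts"`.
#' @param seed RNG seed.
#' @return Parameter tree.
#' @export
initialize_model <- function(spec, part = c("dsn", "expert"),
                             scheme = c("xavier_all", "pretrained_experts"),
                             pretrained = NULL, seed = 1L) {
  part <- match.arg(part)
  scheme <- match.arg(scheme)
  if (part == "expert") {
    return(init_parameters(spec, "expert", seed = seed))
  }
  params <- init_parameters(spec, "dsn", seed = seed)
  if (scheme == "pretrained_experts") {
    if (is.null(pretrained) || length(pretrained) != spec$n_experts) {
      stop("pretrained_experts initialization requires one checkpoint per expert",
         call. = FALSE)
    }
    params$experts <- pretrained
  }
  params
}

adam_state <- function(params) {
  leaves <- flatten_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  pl <- flatten_leaves(params)
  gl <- flatten_leaves(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (j in seq_along(pl)) {
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * gl[[j]]
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * gl[[j]]^2
    pl[[j]] <- pl[[j]] - lr * (state$m[[j]] / bc1) /
      (sqrt(state$v[[j]] / bc2) + eps)
  }
  list(params = unflatten_leaves(params, pl), state = state)
}

model_loss <- function(model, sample, params, spec, with_cache = FALSE) {
  if (model == "dsn") {
    fw <- dsn_forward(sample$input_subvolume, sample$hologram_patch, params,
                      spec, with_cache = with_cache)
  } else {
    fw <- expert_forward(sample$input_subvolume, params, spec,
                         with_cache = with_cache)
  }
  fw$loss <- bce_loss(fw$prob, sample$label_subvolume)
  fw
}

#' Train an expert, generalist or DSN with Adam
#'
#' Minimizes the (optionally L2-regularized) binary cross-entropy by
#' stochastic gradient steps: each iteration draws `batch_size` patch pairs
#' (seeded sampling order, so a fixed seed reproduces the loss history
#' exactly), averages the analytic gradients, and applies one Adam update.
#' Divergence (non-finite loss) aborts with diagnostics.
#'
#' @param model `"expert"` (also used for generalists) or `"dsn"`.
#' @param dataset A `patch_dataset` from [build_dataset()].
#' @param config A [train_config()].
#' @param spec A [dsn_architecture()].
#' @param params Starting parameters; default initializes per
#'   `config$init_scheme`.
#' @param pretrained Expert checkpoints for `"pretrained_experts"`.
#' @param validation Optional `patch_dataset` scored every
#'   `validation_interval` iterations; the returned `best_params` are the
#'   checkpoint with the lowest validation loss (final parameters when no
#'   validation set is given).
#' @param verbose Print progress lines.
#' @return List with `params` (final), `best_params`, `history`
#'   (data.frame of iteration, train and validation loss).
#' @export
train_model <- function(model = c("expert", "dsn"), dataset, config, spec,
                        params = NULL, pretrained = NULL, validation = NULL,
                        verbose = FALSE) {
  model <- match.arg(model)
  if (!length(dataset)) stop("empty training dataset", call. = FALSE)
  if (is.null(params)) {
    params <- initialize_model(spec, part = model, scheme = config$init_scheme,
                               pretrained = pretrained, seed = config$seed)
  }
  state <- adam_state(params)
  history <- data.frame(iteration = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_params <- params
  best_val <- Inf
  set.seed(config$seed + 10000L)
  n <- length(dataset)
  for (it in seq_len(config$max_iterations)) {
    idx <- sample.int(n, config$batch_size, replace = config$batch_size > n)
    grads <- NULL
    loss_acc <- 0
    for (s in idx) {
      fw <- model_loss(model, dataset[[s]], params, spec, with_cache = TRUE)
      loss_acc <- loss_acc + fw$loss
      glogits <- (fw$prob - dataset[[s]]$label_subvolume) /
        (length(fw$prob) * config$batch_size)
      dim(glogits) <- dim(fw$logits)
      g <- if (model == "dsn") {
        dsn_backward(fw, params, glogits, spec)
      } else {
        expert_backward(fw$cache, params, glogits, spec)
      }
      grads <- if (is.null(grads)) g else ptree_map(`+`, grads, g)
    }
    train_loss <- loss_acc / config$batch_size
    if (!is.finite(train_loss)) {
      stop("training diverged at iteration ", it, " (loss = ", train_loss, ")",
           call. = FALSE)
    }
    if (config$l2_gamma > 0) {
      grads <- ptree_map(function(g, w) g + 2 * config$l2_gamma * w,
                         grads, params)
      train_loss <- regularized_loss(train_loss, params, config$l2_gamma)
    }
    upd <- adam_step(params, grads, state, config$learning_rate)
    params <- upd$params
    state <- upd$state
    val_loss <- NA_real_
    if (it %% config$validation_interval == 0L || it == config$max_iterations) {
      if (!is.null(validation) && length(validation)) {
        val_loss <- mean(vapply(validation, function(smp) {
          model_loss(model, smp, params, spec)$loss
        }, numeric(1)))
        if (val_loss < best_val) {
          best_val <- val_loss
          best_params <- params
        }
      }
      if (verbose) {
        message(sprintf("iter %d: train %.4f val %s", it, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      }
    }
    history <- rbind(history,
                     data.frame(iteration = it, train_loss = train_loss,
                                val_loss = val_loss))
  }
  if (is.null(validation)) best_params <- params
  list(params = params, best_params = best_params, history = history)
}

#' Save / load parameter checkpoints
#'
#' The architecture spec travels inside the checkpoint so a model can be
#' restored without external context.
#'
#' @param params Parameter tree.
#' @param spec A [dsn_architecture()].
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(params, spec)`.
#' @export
save_checkpoint <- function(params, spec, path) {
  saveRDS(list(params = params, spec = spec, version = "1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(params = ck$params, spec = ck$spec)
}
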