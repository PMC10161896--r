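#' Training configuration
#'
#' Engineering defaults for the optimization loop: Adam with learning rate
#' 1e-3 (1e-4 for fine-tuning), batch size 8, 100 epochs at package scale.
#' `coefficient_mode = "related"` reproduces the ablation variant trained
#' on approximation + horizontal coefficients only.
#'
#' @param epochs Number of passes over the training split (>= 0; 0 returns
#'   the input model untouched, which is useful for plumbing tests).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size.
#' @param warmup_steps Number of initial optimizer steps over which the
#'   learning rate ramps linearly from 0 to `learning_rate`; damps the
#'   aggressive first Adam steps and makes short runs less
#'   seed-sensitive.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed Seed controlling shuffling (and, via [train()]'s `model`
#'   default, initialization).
#' @param deterministic_mode If `TRUE` (default) the run is a pure
#'   function of its seed.
#' @param coefficient_mode `"complete"` or `"related"`.
#' @param lambda_reg Regularization weight forwarded to [loss_config()].
#' @param loss A [loss_config()]; overrides `lambda_reg` if supplied.
#' @param checkpoint_every Epoch cadence for optional on-disk checkpoints
#'   (0 = never).
#' @param checkpoint_dir Directory for cadence checkpoints.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, learning_rate = 1e-3,
                         warmup_steps = 20L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L, deterministic_mode = TRUE,
                         coefficient_mode = c("complete", "related"),
                         lambda_reg = 0.1, loss = NULL,
                         checkpoint_every = 0L, checkpoint_dir = NULL) {
  coefficient_mode <- match.arg(coefficient_mode)
  if (epochs < 0L) stop("epochs must be non-negative", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be positive", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (is.null(loss)) loss <- loss_config(lambda_reg = lambda_reg)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed),
                 deterministic_mode = isTRUE(deterministic_mode),
                 coefficient_mode = coefficient_mode, loss = loss,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# Records -> list of (input array, label array) pairs. Inputs are the
# corrupted-sinogram coefficients, labels the artifact coefficients;
# under per-sample standardization both are divided by one scalar per
# record (training then happens in normalized units, and
# predict_artifact() rescales at inference).
prepare_tensors <- function(records, input_scale = "per-sample") {
  lapply(records, function(r) {
    x <- coeffs_to_array(r$corrupted_coeffs)
    y <- coeffs_to_array(r$artifact_coeffs)
    if (identical(input_scale, "none")) {
      list(x = x, y = y, scale = 1)
    } else {
      sc <- sample_scale(x)
      list(x = center_bands(x) / sc, y = y / sc, scale = sc)
    }
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  warm <- if (is.null(cfg$warmup_steps) || cfg$warmup_steps <= 0L) 1
          else min(1, state$t / cfg$warmup_steps)
  lr <- cfg$learning_rate * warm
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  list(params = params, state = state)
}

# Mean total_loss of a model over prepared tensors (no gradient).
dataset_loss <- function(model, tensors, loss_cfg) {
  wl <- weights_lists(model)
  related <- model$coefficient_mode == "related"
  mean(vapply(tensors, function(tn) {
    out <- net_forward_cpp(tn$x, wl$W, wl$b, related)
    total_loss(array_to_coeffs(out), array_to_coeffs(tn$y), loss_cfg)
  }, numeric(1)))
}

#' Train the correction network
#'
#' Minimizes the composite objective `L = L_M + lambda * L_W` over the
#' training split by mini-batch Adam, evaluating the validation split each
#' epoch and returning the parameters with the best validation loss. In
#' `"related"` coefficient mode the WV/WD channels are zeroed at the
#' network's input and output, so only the approximation and horizontal
#' coefficients inform the model (the ablation variant). Non-finite losses
#' abort with a `destriper_divergence` error carrying the last finite
#' model.
#'
#' @param model A `correction_model` from [build_model()], or `NULL` to
#'   build one from `cfg` (seeded by `cfg$seed`).
#' @param train_split,val_split Lists of `sample_record`s.
#' @param cfg A [train_config()].
#' @return A `train_fit` list with elements `model` (best checkpoint),
#'   `history` (per-epoch tibble), `cfg` and `provenance`. [tidy()] returns
#'   the history, [glance()] a one-row summary.
#' @export
train <- function(model = NULL, train_split, val_split, cfg = train_config()) {
  if (length(train_split) == 0L) stop("empty training split", call. = FALSE)
  if (length(val_split) == 0L) stop("empty validation split", call. = FALSE)
  if (is.null(model)) {
    model <- build_model(init_seed = cfg$seed,
                         coefficient_mode = cfg$coefficient_mode)
  }
  model$coefficient_mode <- cfg$coefficient_mode
  train_tensors <- prepare_tensors(train_split, model$input_scale)
  val_tensors <- prepare_tensors(val_split, model$input_scale)
  run_training(model, train_tensors, val_tensors, cfg,
               provenance = list(mode = "train"))
}

#' Fine-tune a pretrained checkpoint on a small dataset
#'
#' Transfer-learning path: a network pretrained on the large synthetic
#' dataset is further trained on a small dataset from a different stripe
#' distribution (e.g. beamline data), typically with a reduced learning
#' rate. With few target samples this reaches a better solution than
#' training from random initialization under the same budget.
#'
#' @param pretrained A `correction_model` or the path of a checkpoint file.
#' @param small_split List of `sample_record`s to adapt to.
#' @param cfg A [train_config()]; `cfg$epochs = 0` returns the pretrained
#'   parameters bit-for-bit.
#' @param val_split Optional validation records; defaults to
#'   `small_split`.
#' @return A `train_fit`, with provenance recording the source checkpoint.
#' @export
fine_tune <- function(pretrained, small_split, cfg = train_config(learning_rate = 1e-4),
                      val_split = small_split) {
  source_label <- "in-memory model"
  if (is.character(pretrained)) {
    source_label <- pretrained
    pretrained <- load_checkpoint(pretrained)
  }
  stopifnot(inherits(pretrained, "correction_model"))
  assert_spec_match(pretrained, pretrained$spec)
  if (length(small_split) == 0L) stop("empty fine-tuning split", call. = FALSE)
  model <- pretrained
  model$coefficient_mode <- cfg$coefficient_mode
  run_training(model, prepare_tensors(small_split, model$input_scale),
               prepare_tensors(val_split, model$input_scale),
               cfg, provenance = list(mode = "fine_tune",
                                      source_checkpoint = source_label,
                                      source_provenance = pretrained$provenance))
}

run_training <- function(model, train_tensors, val_tensors, cfg, provenance) {
  params <- flatten_params(model)
  state <- adam_init(params)
  n <- length(train_tensors)
  history <- vector("list", cfg$epochs)
  best_params <- params
  best_val <- Inf
  loss_cfg <- cfg$loss
  t_start <- Sys.time()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- sample.int(n)
      batch_starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (bs in batch_starts) {
        idx <- order_idx[bs:min(bs + cfg$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        wl <- weights_lists(model)
        lc <- loss_cfg_cpp(loss_cfg)
        related <- cfg$coefficient_mode == "related"
        layer_nms <- conv_layer_names(model)
        for (i in idx) {
          tn <- train_tensors[[i]]
          res <- net_grad_cpp(tn$x, tn$y, wl$W, wl$b, related,
                              loss_cfg$lambda_reg, lc$reg_channels,
                              lc$axis, lc$l2)
          if (!is.finite(res$loss)) {
            cond <- structure(
              class = c("destriper_divergence", "error", "condition"),
              list(message = sprintf("non-finite loss at epoch %d; last finite checkpoint attached", epoch),
                   call = sys.call(-1), model = unflatten_params(model, best_params)))
            stop(cond)
          }
          batch_loss <- batch_loss + res$loss
          g <- stats::setNames(
            c(res$gw, res$gb),
            c(paste0(layer_nms, ".w"), paste0(layer_nms, ".b")))[names(params)]
          grads <- if (is.null(grads)) g else purrr::map2(grads, g, `+`)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        upd <- adam_step(params, grads, state, cfg)
        params <- upd$params; state <- upd$state
        model <- unflatten_params(model, params)
        epoch_loss <- epoch_loss + batch_loss
      }
      train_loss <- epoch_loss / n
      val_loss <- dataset_loss(model, val_tensors, loss_cfg)
      if (is.finite(val_loss) && val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
      }
      if (cfg$checkpoint_every > 0L && !is.null(cfg$checkpoint_dir) &&
          epoch %% cfg$checkpoint_every == 0L) {
        save_checkpoint(unflatten_params(model, params),
                        file.path(cfg$checkpoint_dir,
                                  sprintf("epoch-%04d.rds", epoch)))
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
        seed = cfg$seed)
    }
  })
  history <- if (cfg$epochs > 0L) dplyr::bind_rows(history) else
    tibble::tibble(epoch = integer(), train_loss = numeric(),
                   val_loss = numeric(), elapsed_s = numeric(),
                   seed = integer())
  final_model <- unflatten_params(model, best_params)
  final_model$provenance <- utils::modifyList(
    final_model$provenance,
    c(provenance, list(seed = cfg$seed, epochs = cfg$epochs,
                       coefficient_mode = cfg$coefficient_mode,
                       best_val_loss = if (is.finite(best_val)) best_val else NA_real_)))
  structure(list(model = final_model, history = history, cfg = cfg,
                 provenance = final_model$provenance),
            class = "train_fit")
}

#' @export
print.train_fit <- function(x, ...) {
  cat(sprintf("<train_fit> %d epochs, final train loss %.4g, best val loss %.4g (%s mode)\n",
              nrow(x$history),
              if (nrow(x$history)) x$history$train_loss[nrow(x$history)] else NA,
              if (nrow(x$history)) min(x$history$val_loss) else NA,
              x$cfg$coefficient_mode))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-epoch training history
#'
#' @param x A `train_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `train_loss`, `val_loss`,
#'   `elapsed_s`, `seed`.
#' @export
tidy.train_fit <- function(x, ...) x$history

#' One-row training summary
#'
#' @param x A `train_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, first/final training loss, best
#'   validation loss, coefficient mode, seed.
#' @export
glance.train_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    first_train_loss = if (nrow(h)) h$train_loss[1] else NA_real_,
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    best_val_loss = if (nrow(h)) min(h$val_loss) else NA_real_,
    coefficient_mode = x$cfg$coefficient_mode,
    seed = x$cfg$seed)
}

#' Compact configuration for smoke-scale runs
#'
#' The package-scale study conditions used by the worked examples and the
#' end-to-end checks: few epochs on small sinograms, seeded.
#'
#' @param seed Master seed.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param coefficient_mode `"complete"` or `"related"`.
#' @param ... Passed through to [train_config()].
#' @return A `train_config`.
#' @export
smoke_train_config <- function(seed = 1L, epochs = 6L, batch_size = 8L,
                               coefficient_mode = "complete", ...) {
  train_config(epochs = epochs, batch_size = batch_size, learning_rate = 3e-3,
               seed = seed, coefficient_mode = coefficient_mode, ...)
}
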