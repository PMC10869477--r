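#' Training configuration
#'
#' Defaults follow the usual protocol for this architecture family: ADAM with
#' learning rate 0.005 and moment coefficients (0.9, 0.999), up to 500 epochs
#' with early stopping once the validation loss has not improved by more than
#' `plateau_tol` for `patience_epochs` consecutive epochs, best-validation
#' weights restored on stop.
#'
#' @param lr ADAM learning rate.
#' @param beta1,beta2 ADAM moment coefficients.
#' @param max_epochs Epoch cap.
#' @param patience_epochs Early-stopping patience (must be < `max_epochs`).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed governing shuffling, dropout and initialization
#'   of the discriminator.
#' @param adapt_method One of `"none"`, `"dann"`, `"cdan"`, `"cdan_e"`.
#' @param lambda_mode `"schedule"` (sigmoidal ramp over training progress) or
#'   `"constant"`.
#' @param lambda_value Lambda for `"constant"` mode (and the ramp's scale).
#' @param lambda_gamma Steepness of the schedule.
#' @param plateau_tol Minimum validation-loss improvement that resets the
#'   early-stopping counter.
#' @param disc_hidden Hidden-layer widths of the domain discriminator.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.005, beta1 = 0.9, beta2 = 0.999,
                         max_epochs = 500L, patience_epochs = 20L,
                         batch_size = 64L, seed = 1L,
                         adapt_method = c("none", "dann", "cdan", "cdan_e"),
                         lambda_mode = c("schedule", "constant"),
                         lambda_value = 1, lambda_gamma = 10,
                         plateau_tol = 1e-4, disc_hidden = c(128L, 128L)) {
  adapt_method <- match.arg(adapt_method)
  lambda_mode <- match.arg(lambda_mode)
  assert_that(is_scalar_num(lr) && lr > 0, "`lr` must be positive")
  assert_that(beta1 > 0 && beta1 < 1 && beta2 > 0 && beta2 < 1,
              "beta coefficients must lie in (0, 1)")
  assert_that(is_count(max_epochs) && is_count(patience_epochs) &&
                patience_epochs < max_epochs,
              "`patience_epochs` must be a positive integer < `max_epochs`")
  structure(
    list(lr = lr, beta1 = beta1, beta2 = beta2,
         max_epochs = as.integer(max_epochs),
         patience_epochs = as.integer(patience_epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         adapt_method = adapt_method, lambda_mode = lambda_mode,
         lambda_value = lambda_value, lambda_gamma = lambda_gamma,
         plateau_tol = plateau_tol, disc_hidden = as.integer(disc_hidden)),
    class = "train_config"
  )
}

lambda_at <- function(config, progress) {
  if (config$lambda_mode == "constant") return(config$lambda_value)
  config$lambda_value * lambda_schedule(progress, config$lambda_gamma)
}

eval_loss_acc <- function(model, ws, batch_size = 256L) {
  x <- ws$x
  y <- ws$meta$y
  n <- dim(x)[3]
  tot_loss <- 0
  correct <- 0
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    out <- model_forward(model, x[, , idx, drop = FALSE], train = FALSE)
    yl <- y[idx]
    tot_loss <- tot_loss + cross_entropy(out$probs, yl) * length(idx)
    correct <- correct + sum((out$probs[2, ] >= 0.5) == (yl == 1))
    at <- at + batch_size
  }
  c(loss = tot_loss / n, acc = correct / n)
}

check_finite <- function(loss, epoch) {
  assert_that(is.finite(loss),
              sprintf("non-finite training loss at epoch %d", epoch))
}

#' Train the classifier with supervised cross-entropy
#'
#' ADAM on mini-batches; after each epoch the validation loss is evaluated;
#' training stops at `max_epochs` or when the validation loss has not improved
#' by more than `plateau_tol` for `patience_epochs` consecutive epochs, and
#' the best-validation-loss weights are restored. Reproducible from
#' `config$seed`.
#'
#' @param model A `seiz_model` (freshly built or warm).
#' @param train_set,val_set Disjoint `window_set`s; the training set must
#'   contain both classes.
#' @param config A [train_config()].
#' @return A `seiz_fit`: list with `model`, `history` (per-epoch tibble),
#'   `stop_reason` (`"max_epochs"` or `"early_stop"`), `epochs_run`,
#'   `best_val_loss`.
#' @export
train_supervised <- function(model, train_set, val_set,
                             config = train_config()) {
  assert_that(inherits(model, "seiz_model"), "`model` must be a seiz_model")
  assert_that(n_windows(train_set) > 0 && n_windows(val_set) > 0,
              "empty training or validation set")
  assert_that(length(unique(train_set$meta$y)) == 2L,
              "training set must contain both classes")
  x <- train_set$x
  y <- train_set$meta$y
  n <- dim(x)[3]

  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, state = model$state)
  plateau <- 0L
  hist <- vector("list", config$max_epochs)
  stop_reason <- "max_epochs"
  epochs_run <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample(n)
      ep_loss <- 0
      ep_correct <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        bi <- idx[b0:min(n, b0 + config$batch_size - 1L)]
        fwd <- model_forward(model, x[, , bi, drop = FALSE], train = TRUE)
        model$state <- fwd$state
        yb <- y[bi]
        loss <- cross_entropy(fwd$probs, yb)
        check_finite(loss, epoch)
        grads <- model_backward(model, fwd, cross_entropy_grad(fwd$probs, yb))
        stp <- adam_step(model$params, grads, opt, config$lr, config$beta1,
                         config$beta2)
        model$params <- stp$params
        opt <- stp$state
        ep_loss <- ep_loss + loss * length(bi)
        ep_correct <- ep_correct + sum((fwd$probs[2, ] >= 0.5) == (yb == 1))
      }
      va <- eval_loss_acc(model, val_set)
      epochs_run <- epoch
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = va[["loss"]], val_acc = va[["acc"]])
      if (va[["loss"]] < best$loss - config$plateau_tol) {
        best <- list(loss = va[["loss"]], params = model$params,
                     state = model$state)
        plateau <- 0L
      } else {
        plateau <- plateau + 1L
        if (plateau >= config$patience_epochs) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  if (is.finite(best$loss)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(
    list(model = model, history = dplyr::bind_rows(hist[seq_len(epochs_run)]),
         stop_reason = stop_reason, epochs_run = epochs_run,
         best_val_loss = best$loss, adapt_method = "none"),
    class = "seiz_fit")
}

#' Train with adversarial domain adaptation (DANN / CDAN / CDAN+E)
#'
#' Each optimization step consumes one labeled source batch and one unlabeled
#' target batch (the smaller side cycling); the classifier minimizes the
#' source cross-entropy while the encoder and a domain discriminator play the
#' adversarial game selected by `config$adapt_method`. Target labels are
#' never read — the target argument carries windows only, and if a labeled
#' `window_set` is passed its labels are dropped at the door. Early stopping
#' monitors the source-domain validation loss (target labels being
#' unavailable by definition).
#'
#' @param model A `seiz_model`.
#' @param source_train,source_val Disjoint labeled source `window_set`s.
#' @param target_unlabeled Target-domain windows: a `window_set` (labels
#'   dropped) or a `(C, T, n)` array.
#' @param config A [train_config()] with `adapt_method != "none"` (with
#'   `"none"` this delegates to [train_supervised()] with a notice).
#' @return A `seiz_fit` whose history additionally carries `domain_loss` and
#'   `lambda`.
#' @export
train_adapted <- function(model, source_train, source_val, target_unlabeled,
                          config = train_config(adapt_method = "dann")) {
  if (config$adapt_method == "none") {
    rlang::inform("adapt_method = 'none': delegating to train_supervised()")
    return(train_supervised(model, source_train, source_val, config))
  }
  assert_that(n_windows(source_train) > 0 && n_windows(source_val) > 0,
              "empty source training or validation set")
  xt <- if (inherits(target_unlabeled, "window_set")) {
    target_unlabeled$x
  } else {
    target_unlabeled
  }
  assert_that(dim(xt)[3] > 0, "empty target set")

  x <- source_train$x
  y <- source_train$meta$y
  n <- dim(x)[3]
  nt <- dim(xt)[3]
  d <- embedding_dim(model$config)
  din <- if (config$adapt_method == "dann") d else d * model$config$n_classes

  disc <- build_discriminator(din, hidden = config$disc_hidden,
                              seed = derive_seed(config$seed, 7L))
  opt_m <- adam_init(model$params)
  opt_d <- adam_init(disc$params)
  best <- list(loss = Inf, params = model$params, state = model$state)
  plateau <- 0L
  hist <- vector("list", config$max_epochs)
  stop_reason <- "max_epochs"
  epochs_run <- 0L
  steps_per_epoch <- length(seq(1L, n, by = config$batch_size))
  total_steps <- steps_per_epoch * config$max_epochs
  step <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample(n)
      idx_t <- sample(nt)
      t_at <- 0L
      ep_task <- 0
      ep_dom <- 0
      ep_correct <- 0
      lam <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        bi <- idx[b0:min(n, b0 + config$batch_size - 1L)]
        # target batch of the same nominal size, cycling
        ti <- integer(0)
        need <- config$batch_size
        while (need > 0L) {
          take <- min(need, nt - t_at)
          ti <- c(ti, idx_t[t_at + seq_len(take)])
          t_at <- t_at + take
          if (t_at >= nt) {
            idx_t <- sample(nt)
            t_at <- 0L
          }
          need <- need - take
        }
        step <- step + 1L
        lam <- lambda_at(config, step / total_steps)
        batch <- domain_batch(x[, , bi, drop = FALSE], y[bi],
                              xt[, , ti, drop = FALSE])
        terms <- da_loss_core(model, disc, batch, lam,
                              method = config$adapt_method, train = TRUE)
        check_finite(terms$task_loss + terms$domain_loss, epoch)
        gr <- attr(terms, "grads")
        model$state <- gr$state
        stp <- adam_step(model$params, gr$model, opt_m, config$lr,
                         config$beta1, config$beta2)
        model$params <- stp$params
        opt_m <- stp$state
        stp <- adam_step(disc$params, gr$disc, opt_d, config$lr,
                         config$beta1, config$beta2)
        disc$params <- stp$params
        opt_d <- stp$state
        ep_task <- ep_task + terms$task_loss * length(bi)
        ep_dom <- ep_dom + terms$domain_loss
        ep_correct <- ep_correct +
          sum((terms$source_probs[2, ] >= 0.5) == (y[bi] == 1))
      }
      va <- eval_loss_acc(model, source_val)
      epochs_run <- epoch
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_task / n, train_acc = ep_correct / n,
        val_loss = va[["loss"]], val_acc = va[["acc"]],
        domain_loss = ep_dom / steps_per_epoch, lambda = lam)
      if (va[["loss"]] < best$loss - config$plateau_tol) {
        best <- list(loss = va[["loss"]], params = model$params,
                     state = model$state)
        plateau <- 0L
      } else {
        plateau <- plateau + 1L
        if (plateau >= config$patience_epochs) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  if (is.finite(best$loss)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(
    list(model = model, history = dplyr::bind_rows(hist[seq_len(epochs_run)]),
         stop_reason = stop_reason, epochs_run = epochs_run,
         best_val_loss = best$loss, adapt_method = config$adapt_method,
         discriminator = disc),
    class = "seiz_fit")
}

#' @export
print.seiz_fit <- function(x, ...) {
  cat(sprintf(
    "<seiz_fit> %s, %d epoch(s), stop: %s, best val loss %.4f\n",
    if (x$adapt_method == "none") "supervised" else x$adapt_method,
    x$epochs_run, x$stop_reason, x$best_val_loss))
  invisible(x)
}
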