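#' Architecture configuration for the compact EEG classifier
#'
#' The classifier has three convolutional blocks: `F1` temporal filters of
#' length `kernel1` (linear, no bias) that learn frequency content, a
#' depthwise spatial convolution over the full channel axis with multiplier
#' `F2` (spatial filters per temporal filter), and `F3` feature filters of
#' length `kernel2` applied after the `F2*F1` maps are folded into the spatial
#' axis of a single map. Each block carries batch normalization; the second
#' and third add ReLU, temporal average pooling by `pool`, and dropout. A
#' dense softmax layer closes the network. Convolutions use "same" zero
#' padding in time, so after the two pooling stages the flattened embedding
#' has dimension `F3 * F2 * F1 * (T / pool / pool)`.
#'
#' @param C Channel count.
#' @param T Samples per window (must be divisible by `pool^2`).
#' @param F1 Temporal filter count.
#' @param F2 Depthwise multiplier (spatial filters per temporal filter).
#' @param F3 Feature filter count.
#' @param n_classes Number of classes (fixed at 2).
#' @param dropout_p Dropout probability.
#' @param pool Temporal pooling factor of both pooling stages.
#' @param kernel1,kernel2 Temporal kernel lengths of the first and third
#'   convolutions.
#' @return A `model_config` list.
#' @export
model_config <- function(C, T, F1 = 8L, F2 = 2L, F3 = 16L, n_classes = 2L,
                         dropout_p = 0.25, pool = 16L,
                         kernel1 = 128L, kernel2 = 64L) {
  assert_that(is_count(C), "`C` must be a positive integer")
  assert_that(is_count(T), "`T` must be a positive integer")
  assert_that(is_count(F1) && is_count(F2) && is_count(F3),
              "F1, F2, F3 must be positive integers")
  assert_that(n_classes == 2L, "only binary classification is supported (N = 2)")
  assert_that(is_scalar_num(dropout_p) && dropout_p >= 0 && dropout_p < 1,
              "`dropout_p` must be in [0, 1)")
  assert_that(T %% pool == 0 && (T %/% pool) %% pool == 0,
              sprintf("T = %d is not divisible by pool = %d at both pooling stages (T must be a multiple of %d)",
                      T, pool, pool * pool))
  structure(
    list(C = as.integer(C), T = as.integer(T), F1 = as.integer(F1),
         F2 = as.integer(F2), F3 = as.integer(F3),
         n_classes = as.integer(n_classes), dropout_p = dropout_p,
         pool = as.integer(pool), kernel1 = as.integer(kernel1),
         kernel2 = as.integer(kernel2)),
    class = "model_config"
  )
}

#' Embedding (flatten-layer) dimension for a configuration
#' @param config A [model_config()].
#' @return Integer embedding dimension `F3 * F2 * F1 * (T / pool^2)`.
#' @export
embedding_dim <- function(config) {
  t2 <- config$T %/% config$pool %/% config$pool
  config$F3 * config$F2 * config$F1 * t2
}

#' Per-layer output shapes of the classifier
#'
#' @param config A [model_config()].
#' @return A tibble with `layer` and `output` (list of integer vectors) in the
#'   conventional `(maps, height, width)` order.
#' @export
model_shapes <- function(config) {
  C <- config$C; T <- config$T
  F1 <- config$F1; F2 <- config$F2; F3 <- config$F3
  t1 <- T %/% config$pool
  t2 <- t1 %/% config$pool
  tibble::tibble(
    layer = c("input", "conv_temporal", "batchnorm1", "conv_depthwise",
              "batchnorm2", "relu1", "avgpool1", "dropout1", "conv_feature",
              "batchnorm3", "relu2", "avgpool2", "dropout2", "flatten",
              "dense_softmax"),
    output = list(
      c(1L, C, T), c(F1, C, T), c(F1, C, T), c(F2 * F1, 1L, T),
      c(F2 * F1, 1L, T), c(F2 * F1, 1L, T), c(F2 * F1, 1L, t1),
      c(F2 * F1, 1L, t1), c(F3, F2 * F1, t1), c(F3, F2 * F1, t1),
      c(F3, F2 * F1, t1), c(F3, F2 * F1, t2), c(F3, F2 * F1, t2),
      F3 * F2 * F1 * t2, config$n_classes)
  )
}

#' Per-layer trainable parameter counts
#'
#' Trainable weights only: the convolutions carry no bias (batch normalization
#' supplies the affine shift), each batch-norm layer has a gain and a shift
#' per map, and the dense layer includes its bias.
#'
#' @param config A [model_config()].
#' @return A tibble with `layer` and `n_params`.
#' @export
model_param_counts <- function(config) {
  d <- embedding_dim(config)
  tibble::tibble(
    layer = c("conv_temporal", "batchnorm1", "conv_depthwise", "batchnorm2",
              "conv_feature", "batchnorm3", "dense"),
    n_params = c(config$kernel1 * config$F1,
                 2L * config$F1,
                 config$C * config$F2 * config$F1,
                 2L * config$F2 * config$F1,
                 config$kernel2 * config$F3,
                 2L * config$F3,
                 (d + 1L) * config$n_classes)
  )
}

#' Build (initialize) a classifier
#'
#' Weights are drawn He-style (convolutions) and Glorot-style (dense) from a
#' seeded RNG, so building twice with the same config and seed yields
#' identical models.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `seiz_model` object.
#' @export
build_model <- function(config, seed = 1L) {
  assert_that(inherits(config, "model_config"),
              "`config` must come from model_config()")
  C <- config$C; F1 <- config$F1; F2 <- config$F2; F3 <- config$F3
  M <- F1 * F2
  D <- embedding_dim(config)
  params <- with_seed(seed, list(
    w1 = matrix(stats::rnorm(config$kernel1 * F1, sd = sqrt(2 / config$kernel1)),
                config$kernel1, F1),
    bn1_gamma = rep(1, F1), bn1_beta = rep(0, F1),
    wd = array(stats::rnorm(C * F2 * F1, sd = sqrt(2 / C)), c(C, F2, F1)),
    bn2_gamma = rep(1, M), bn2_beta = rep(0, M),
    w3 = matrix(stats::rnorm(config$kernel2 * F3, sd = sqrt(2 / config$kernel2)),
                config$kernel2, F3),
    bn3_gamma = rep(1, F3), bn3_beta = rep(0, F3),
    wfc = matrix(stats::rnorm(config$n_classes * D, sd = sqrt(2 / (D + config$n_classes))),
                 config$n_classes, D),
    bfc = rep(0, config$n_classes)
  ))
  state <- list(bn1_rm = rep(0, F1), bn1_rv = rep(1, F1),
                bn2_rm = rep(0, M), bn2_rv = rep(1, M),
                bn3_rm = rep(0, F3), bn3_rv = rep(1, F3))
  structure(list(config = config, params = params, state = state),
            class = "seiz_model")
}

#' @export
print.seiz_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seiz_model> C=%d T=%d F1=%d F2=%d F3=%d (embedding dim %d, %d trainable parameters)\n",
    cfg$C, cfg$T, cfg$F1, cfg$F2, cfg$F3, embedding_dim(cfg),
    sum(model_param_counts(cfg)$n_params)))
  invisible(x)
}

#' Total and per-tensor trainable parameter counts of a built model
#' @param model A `seiz_model`.
#' @return Named integer vector of per-tensor element counts.
#' @export
count_params <- function(model) {
  vapply(model$params, length, 0L)
}
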