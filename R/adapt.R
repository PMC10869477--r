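# Feature-based adversarial domain adaptation: DANN, CDAN and CDAN+E heads
# and loss assembly over the classifier's (features, probs).
#
# Conventions (documented here once):
#  * domain labels: source = 0, target = 1;
#  * domain loss = per-side batch mean of the discriminator's binary
#    cross-entropy, the two sides summed — an untrained discriminator
#    emitting 0.5 everywhere scores 2*ln(2);
#  * the encoder receives the domain-loss gradient multiplied by -lambda
#    (gradient reversal), the discriminator the plain gradient: the standard
#    adversarial saddle between encoder and discriminator;
#  * classifier probabilities entering the multilinear map and the entropy
#    weights are detached (no gradient flows back through them).

#' Gradient reversal layer
#'
#' The identity map in the forward direction; during backpropagation the
#' upstream gradient is multiplied by `-lambda_`. This single sign flip is
#' what turns a jointly minimized classifier/discriminator stack into the
#' adversarial min-max game: the discriminator descends its domain loss while
#' the encoder ascends it.
#'
#' @param x Numeric input (any shape).
#' @param lambda_ Non-negative trade-off multiplier.
#' @return `x`, tagged with the reversal multiplier; pass through
#'   [grl_backward()] to propagate gradients.
#' @export
grad_reverse <- function(x, lambda_ = 1) {
  assert_that(is_scalar_num(lambda_) && lambda_ >= 0,
              "`lambda_` must be a non-negative scalar")
  structure(x, grl_lambda = lambda_, class = c("grad_reverse", class(x)))
}

#' Backward rule of the gradient reversal layer
#' @param x An object returned by [grad_reverse()].
#' @param upstream Gradient arriving from above (same shape as `x`).
#' @return `-lambda_ * upstream`.
#' @export
grl_backward <- function(x, upstream) {
  lam <- attr(x, "grl_lambda")
  assert_that(!is.null(lam), "`x` must come from grad_reverse()")
  -lam * upstream
}

#' Multilinear (outer-product) map of features and class predictions
#'
#' The joint variable fed to the conditional discriminator: the outer product
#' of the feature embedding and the predicted class distribution, flattened
#' feature-major, so `h[(j-1)*c + m] = f_j * g_m`. Its Euclidean norm equals
#' `||f|| * ||g||`.
#'
#' @param features Numeric vector (length d) or n x d matrix.
#' @param probs Numeric vector (length c) or n x c matrix of class
#'   probabilities.
#' @return A length `d*c` vector, or an n x (d*c) matrix.
#' @export
multilinear_map <- function(features, probs) {
  if (is.vector(features)) {
    assert_that(is.vector(probs), "vector features need vector probs")
    return(as.vector(t(outer(features, probs))))
  }
  assert_that(nrow(features) == nrow(probs),
              "features and probs must have matching example counts")
  d <- ncol(features); cc <- ncol(probs)
  out <- matrix(0, nrow(features), d * cc)
  for (m in seq_len(cc)) {
    out[, (seq_len(d) - 1L) * cc + m] <- features * probs[, m]
  }
  out
}

#' Entropy-based example weight for conditional adversarial training
#'
#' `w = 1 + exp(-H(p))` with `H(p) = -sum p_i log p_i` (natural log,
#' `0 * log 0 = 0`): confident predictions (low entropy) get weight near 2,
#' maximally uncertain two-class predictions get 1.5. For two classes the
#' weight always lies in `[1.5, 2]` (and in `(1, 2]` for any class count).
#'
#' @param probs Simplex vector, or matrix with one distribution per row.
#' @return Scalar weight, or vector of weights (one per row).
#' @export
entropy_weight <- function(probs) {
  h_of <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (is.matrix(probs)) {
    h <- apply(probs, 1, h_of)
  } else {
    h <- h_of(probs)
  }
  1 + exp(-h)
}

#' Trade-off schedule for the adversarial loss weight
#'
#' `lambda(progress) = 2 / (1 + exp(-gamma * progress)) - 1`, rising smoothly
#' from 0 to ~1 over training so early noisy discriminator gradients do not
#' destabilize the encoder.
#'
#' @param progress Training progress fraction in `[0, 1]`.
#' @param gamma Steepness (default 10).
#' @return The scheduled lambda value.
#' @export
lambda_schedule <- function(progress, gamma = 10) {
  assert_that(all(progress >= 0 & progress <= 1),
              "`progress` must lie in [0, 1]")
  2 / (1 + exp(-gamma * progress)) - 1
}

#' Bundle a source/target batch for adversarial training
#' @param xs Labeled source windows, `(C, T, n_s)` array or `window_set`.
#' @param ys Integer 0/1 source labels (taken from `xs` if it is a
#'   `window_set`).
#' @param xt Unlabeled target windows, `(C, T, n_t)` array or `window_set`
#'   (labels, if present, are dropped and never read).
#' @return A `domain_batch` list.
#' @export
domain_batch <- function(xs, ys = NULL, xt) {
  if (inherits(xs, "window_set")) {
    ys <- ys %||% xs$meta$y
    xs <- xs$x
  }
  if (inherits(xt, "window_set")) xt <- xt$x
  assert_that(!is.null(ys), "source labels `ys` are required")
  assert_that(dim(xs)[3] > 0 && dim(xt)[3] > 0,
              "both source and target sides must be non-empty")
  assert_that(all(dim(xs)[1:2] == dim(xt)[1:2]),
              "source and target windows must share (C, T)")
  assert_that(all(ys %in% c(0, 1)), "source labels must be 0/1")
  structure(list(xs = xs, ys = as.integer(ys), xt = xt),
            class = "domain_batch")
}

# Core loss/gradient assembly shared by dann_loss and cdan_loss.
# Returns DALossTerms plus (attr) the gradients for model and discriminator.
da_loss_core <- function(model, discriminator, batch, lambda_,
                         method = c("dann", "cdan", "cdan_e"),
                         train = TRUE) {
  method <- match.arg(method)
  assert_that(inherits(batch, "domain_batch"),
              "`batch` must come from domain_batch()")
  assert_that(is_scalar_num(lambda_) && lambda_ >= 0,
              "`lambda_` must be a non-negative scalar")
  ns <- dim(batch$xs)[3]
  nt <- dim(batch$xt)[3]

  # Separate encoder passes per domain (each with its own batch statistics),
  # so lambda = 0 reduces exactly to supervised training on the source batch.
  fs <- model_forward(model, batch$xs, train = train)
  model$state <- fs$state
  ft <- model_forward(model, batch$xt, train = train)

  task_loss <- cross_entropy(fs$probs, batch$ys)
  dlogits_s <- cross_entropy_grad(fs$probs, batch$ys)

  d <- nrow(fs$features)
  if (method == "dann") {
    din_s <- fs$features
    din_t <- ft$features
  } else {
    exp_dim <- d * model$config$n_classes
    assert_that(discriminator$input_dim == exp_dim,
                sprintf("discriminator input_dim %d does not match d*c = %d",
                        discriminator$input_dim, exp_dim))
    din_s <- cdan_input(fs$features, fs$probs)
    din_t <- cdan_input(ft$features, ft$probs)
  }
  assert_that(discriminator$input_dim == nrow(din_s),
              sprintf("discriminator input_dim %d does not match head input %d",
                      discriminator$input_dim, nrow(din_s)))

  dfwd <- disc_forward(discriminator, cbind(din_s, din_t))
  p_dom <- dfwd$prob
  dom <- c(rep(0, ns), rep(1, nt))

  weights <- rep(1, ns + nt)
  if (method == "cdan_e") {
    # uncertainty weights, detached from the classifier's gradient
    weights <- c(entropy_weight(t(fs$probs)), entropy_weight(t(ft$probs)))
  }
  bce <- -(dom * log(p_dom) + (1 - dom) * log(1 - p_dom))
  side_n <- ifelse(dom == 0, ns, nt)
  domain_loss <- sum(weights * bce / side_n)

  # d(domain_loss)/d(logit) with the per-side mean convention
  dz <- weights * (p_dom - dom) / side_n
  dback <- disc_backward(discriminator, dfwd, dz)

  gx <- dback$gx
  if (method == "dann") {
    gf_s <- gx[, seq_len(ns), drop = FALSE]
    gf_t <- gx[, ns + seq_len(nt), drop = FALSE]
  } else {
    gf_s <- cdan_input_backward(gx[, seq_len(ns), drop = FALSE], fs$probs, d)
    gf_t <- cdan_input_backward(gx[, ns + seq_len(nt), drop = FALSE],
                                ft$probs, d)
  }

  # gradient reversal into the encoder
  g_model_s <- model_backward(model, fs, dlogits_s,
                              dfeat_extra = -lambda_ * gf_s)
  g_model_t <- model_backward(model, ft,
                              matrix(0, model$config$n_classes, nt),
                              dfeat_extra = -lambda_ * gf_t)
  g_model <- mapply(function(a, b) a + b, g_model_s, g_model_t,
                    SIMPLIFY = FALSE)

  terms <- structure(
    list(task_loss = task_loss, domain_loss = domain_loss,
         lambda_ = lambda_, weights = weights, method = method,
         domain_probs = p_dom, source_probs = fs$probs),
    class = "da_loss_terms")
  attr(terms, "grads") <- list(model = g_model, disc = dback$grads,
                               state = ft$state)
  terms
}

# Multilinear map in column layout: features (d, n), probs (c, n) ->
# (d*c, n) with h[(j-1)*c + m] = f_j * g_m. probs are treated as constants.
cdan_input <- function(features, probs) {
  d <- nrow(features); cc <- nrow(probs); n <- ncol(features)
  out <- matrix(0, d * cc, n)
  for (m in seq_len(cc)) {
    out[(seq_len(d) - 1L) * cc + m, ] <-
      features * rep(probs[m, ], each = d)
  }
  out
}

cdan_input_backward <- function(gh, probs, d) {
  cc <- nrow(probs)
  gf <- matrix(0, d, ncol(gh))
  for (m in seq_len(cc)) {
    gf <- gf + gh[(seq_len(d) - 1L) * cc + m, , drop = FALSE] *
      rep(probs[m, ], each = d)
  }
  gf
}

#' DANN loss terms on a source/target batch
#'
#' Task loss is the cross-entropy of the classifier on the labeled source
#' windows; domain loss is the discriminator's binary cross-entropy on the
#' feature embeddings of both domains (source = 0, target = 1). The encoder
#' receives the domain gradient through gradient reversal scaled by
#' `-lambda_` — the adversarial saddle. Gradients for both players are
#' attached as `attr(, "grads")`.
#'
#' @param model A `seiz_model`.
#' @param discriminator A [build_discriminator()] with `input_dim` equal to
#'   the embedding dimension.
#' @param batch A [domain_batch()].
#' @param lambda_ Trade-off multiplier (>= 0).
#' @param train Use training-mode forward passes (batch statistics, dropout).
#' @return A `da_loss_terms` list: `task_loss`, `domain_loss`, `lambda_`,
#'   `weights` (all ones for DANN).
#' @export
dann_loss <- function(model, discriminator, batch, lambda_, train = TRUE) {
  da_loss_core(model, discriminator, batch, lambda_, "dann", train)
}

#' CDAN / CDAN+E loss terms on a source/target batch
#'
#' As [dann_loss()], but the discriminator consumes the multilinear map of
#' features and (detached) predicted class distributions, so alignment is
#' conditioned on the classifier's prediction. With `entropy_conditioning`,
#' each example's discriminator loss term is multiplied by the detached
#' uncertainty weight `1 + exp(-H(p))` (in `[1.5, 2]` for two classes).
#'
#' @inheritParams dann_loss
#' @param entropy_conditioning Use entropy weights (the CDAN+E variant).
#' @return A `da_loss_terms` list.
#' @export
cdan_loss <- function(model, discriminator, batch, lambda_,
                      entropy_conditioning = FALSE, train = TRUE) {
  da_loss_core(model, discriminator, batch, lambda_,
               if (entropy_conditioning) "cdan_e" else "cdan", train)
}
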