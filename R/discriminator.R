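#' Build a domain discriminator
#'
#' A multilayer perceptron with ReLU hidden layers and a sigmoid output
#' giving the probability that an example comes from the target domain
#' (source = 0, target = 1). For feature-level adaptation (DANN) the input
#' dimension is the embedding dimension `d`; for conditional adaptation
#' (CDAN, CDAN+E) it is `d * n_classes`, the size of the multilinear map.
#'
#' @param input_dim Input dimension.
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed Integer seed for weight initialization.
#' @return A `seiz_discriminator` object.
#' @export
build_discriminator <- function(input_dim, hidden = c(128L, 128L), seed = 1L) {
  assert_that(is_count(input_dim), "`input_dim` must be a positive integer")
  assert_that(length(hidden) >= 1L, "at least one hidden layer is required")
  dims <- c(input_dim, hidden, 1L)
  params <- with_seed(seed, {
    out <- list()
    for (l in seq_len(length(dims) - 1L)) {
      out[[paste0("W", l)]] <- matrix(
        stats::rnorm(dims[l + 1] * dims[l], sd = sqrt(2 / dims[l])),
        dims[l + 1], dims[l])
      out[[paste0("b", l)]] <- rep(0, dims[l + 1])
    }
    out
  })
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), params = params,
                 n_layers = length(dims) - 1L),
            class = "seiz_discriminator")
}

# Forward: x is (input_dim, n). Returns output probabilities in (0,1) and the
# per-layer cache for backprop.
disc_forward <- function(disc, x) {
  p <- disc$params
  acts <- list(x)
  h <- x
  for (l in seq_len(disc$n_layers)) {
    z <- p[[paste0("W", l)]] %*% h + p[[paste0("b", l)]]
    h <- if (l < disc$n_layers) pmax(z, 0) else z
    acts[[l + 1L]] <- h
  }
  prob <- 1 / (1 + exp(-as.numeric(h)))
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  list(prob = prob, acts = acts)
}

# Backward from the gradient at the output logit (1 x n). Returns parameter
# gradients and the gradient at the input (input_dim x n).
disc_backward <- function(disc, cache, dz_out) {
  p <- disc$params
  grads <- list()
  g <- matrix(dz_out, 1)
  for (l in rev(seq_len(disc$n_layers))) {
    a_in <- cache$acts[[l]]
    grads[[paste0("W", l)]] <- g %*% t(a_in)
    grads[[paste0("b", l)]] <- rowSums(g)
    g <- t(p[[paste0("W", l)]]) %*% g
    if (l > 1L) g <- g * (cache$acts[[l]] > 0)
  }
  list(grads = grads[names(p)], gx = g)
}
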