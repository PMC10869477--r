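test_that("gradient reversal is the identity forward and -lambda backward", {
  withr::with_seed(1, x <- matrix(rnorm(12), 3, 4))
  for (lam in c(0, 0.5, 1, 2)) {
    y <- grad_reverse(x, lam)
    expect_equal(unclass(y)[seq_along(x)], x[seq_along(x)])
    # finite differences of sum(forward(x)) give 1 everywhere; the layer's
    # backward rule must return -lambda * that upstream gradient
    eps <- 1e-7
    fd <- (sum(x + eps) - sum(x - eps)) / (2 * eps * length(x))
    g <- grl_backward(y, matrix(fd, 3, 4))
    expect_equal(g, matrix(-lam * 1, 3, 4), tolerance = 1e-5)
  }
  expect_seiz_error(grad_reverse(x, -1))
})

test_that("lambda = 0 reduces adversarial gradients to supervised training", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, 5)
  withr::with_seed(2, {
    xs <- array(rnorm(3 * 32 * 6), c(3, 32, 6))
    xt <- array(rnorm(3 * 32 * 6), c(3, 32, 6))
  })
  ys <- rep(c(0, 1), 3)
  disc <- build_discriminator(embedding_dim(cfg), hidden = c(8), seed = 1)
  terms <- dann_loss(model, disc, domain_batch(xs, ys, xt), lambda_ = 0)
  gr <- attr(terms, "grads")$model

  fwd <- seizadapt:::model_forward(model, xs, train = TRUE)
  sup <- seizadapt:::model_backward(
    model, fwd, seizadapt:::cross_entropy_grad(fwd$probs, ys))
  for (nm in names(sup)) {
    expect_equal(gr[[nm]], sup[[nm]], tolerance = 1e-12)
  }
  expect_equal(terms$task_loss,
               seizadapt:::cross_entropy(fwd$probs, ys), tolerance = 1e-12)
})

test_that("multilinear map equals the flattened outer product", {
  expect_equal(multilinear_map(c(1, 2), c(0.3, 0.7)),
               c(0.3, 0.7, 0.6, 1.4))
  f <- c(2, -1, 4)
  expect_equal(multilinear_map(f, c(1, 0)), c(2, 0, -1, 0, 4, 0))
  withr::with_seed(3, {
    for (i in 1:10) {
      f <- rnorm(sample(2:9, 1))
      g <- runif(2)
      g <- g / sum(g)
      h <- multilinear_map(f, g)
      oracle <- as.vector(t(f %o% g))   # independent outer-product oracle
      expect_equal(h, oracle, tolerance = 1e-12)
      expect_equal(sqrt(sum(h^2)), sqrt(sum(f^2)) * sqrt(sum(g^2)),
                   tolerance = 1e-6)
    }
  })
  # matrix form: one row per example
  fm <- matrix(1:6, 2, 3)
  gm <- matrix(c(0.5, 1, 0.5, 0), 2, 2)
  hm <- multilinear_map(fm, gm)
  expect_equal(hm[1, ], multilinear_map(fm[1, ], gm[1, ]))
  expect_equal(hm[2, ], multilinear_map(fm[2, ], gm[2, ]))
})

test_that("entropy weights follow 1 + exp(-H) with the 0 log 0 convention", {
  expect_equal(entropy_weight(c(1, 0)), 2)
  expect_equal(entropy_weight(c(0.5, 0.5)), 1.5)
  ps <- seq(0.5, 0.999, length.out = 25)
  h <- -(ps * log(ps) + (1 - ps) * log(1 - ps))
  w <- vapply(ps, function(p) entropy_weight(c(p, 1 - p)), 0)
  expect_equal(w, 1 + exp(-h))
  # strictly decreasing in entropy, bounded in [1.5, 2] for two classes
  expect_true(all(diff(w[order(h)]) < 0))
  expect_true(all(w >= 1.5 & w <= 2))
  wm <- entropy_weight(rbind(c(1, 0), c(0.5, 0.5)))
  expect_equal(wm, c(2, 1.5))
})

test_that("an uninformative discriminator scores 2 ln 2 domain loss", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, 5)
  withr::with_seed(2, {
    xs <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
    xt <- array(rnorm(3 * 32 * 3), c(3, 32, 3))
  })
  disc <- build_discriminator(embedding_dim(cfg), hidden = c(8), seed = 1)
  # zero the output layer: sigmoid(0) = 0.5 for every example
  disc$params$W2[] <- 0
  disc$params$b2[] <- 0
  terms <- dann_loss(model, disc, domain_batch(xs, c(0, 1, 0, 1), xt), 1)
  expect_equal(terms$domain_loss, 2 * log(2), tolerance = 1e-12)
  expect_equal(terms$weights, rep(1, 7))
})

test_that("with one-hot predictions CDAN equals DANN on class-masked blocks", {
  withr::with_seed(4, f <- matrix(rnorm(10), 5, 2))   # (d, n)
  g <- matrix(c(1, 0, 0, 1), 2, 2)                    # one-hot per example
  h <- seizadapt:::cdan_input(f, g)
  # class-0 example occupies the class-0 interleaved block, zeros elsewhere
  expect_equal(h[seq(1, 9, by = 2), 1], f[, 1])
  expect_equal(h[seq(2, 10, by = 2), 1], rep(0, 5))
  expect_equal(h[seq(2, 10, by = 2), 2], f[, 2])
  expect_equal(h[seq(1, 9, by = 2), 2], rep(0, 5))
})

test_that("uniform predictions make CDAN+E exactly 1.5 x CDAN", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, 5)
  # zero dense layer -> logits 0 -> perfectly uniform class probabilities
  model$params$wfc[] <- 0
  model$params$bfc[] <- 0
  withr::with_seed(2, {
    xs <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
    xt <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
  })
  batch <- domain_batch(xs, c(0, 1, 0, 1), xt)
  disc <- build_discriminator(embedding_dim(cfg) * 2, hidden = c(8),
                              seed = 1)
  t_c <- cdan_loss(model, disc, batch, 1, entropy_conditioning = FALSE)
  t_e <- cdan_loss(model, disc, batch, 1, entropy_conditioning = TRUE)
  expect_equal(t_e$weights, rep(1.5, 8))
  expect_equal(t_e$domain_loss, 1.5 * t_c$domain_loss, tolerance = 1e-12)
  g_c <- attr(t_c, "grads")
  g_e <- attr(t_e, "grads")
  for (nm in names(g_c$disc)) {
    expect_equal(g_e$disc[[nm]], 1.5 * g_c$disc[[nm]], tolerance = 1e-12)
  }
})

test_that("discriminator dimension mismatches are rejected", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, 5)
  withr::with_seed(2, {
    xs <- array(rnorm(3 * 32 * 2), c(3, 32, 2))
  })
  batch <- domain_batch(xs, c(0, 1), xs)
  d_feat <- build_discriminator(embedding_dim(cfg), hidden = c(4), seed = 1)
  expect_seiz_error(cdan_loss(model, d_feat, batch, 1), "input_dim")
  d_wrong <- build_discriminator(17, hidden = c(4), seed = 1)
  expect_seiz_error(dann_loss(model, d_wrong, batch, 1), "input_dim")
})

test_that("the lambda schedule follows its sigmoidal closed form", {
  expect_equal(lambda_schedule(0), 0)
  expect_equal(lambda_schedule(1, gamma = 10), 2 / (1 + exp(-10)) - 1,
               tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(lambda_schedule(p)) >= 0))
  expect_seiz_error(lambda_schedule(1.5))
})

test_that("a discriminator separates shifted features but not matched ones", {
  # train the probe on one draw, score domain accuracy on a held-out draw
  train_probe <- function(delta, seed) {
    withr::with_seed(seed, {
      n <- 150
      d <- 8
      fs <- matrix(rnorm(2 * n * d), d)
      ft <- matrix(rnorm(2 * n * d, mean = delta), d)
    })
    tr <- seq_len(150)
    te <- 150 + seq_len(150)
    disc <- build_discriminator(d, hidden = c(16), seed = seed)
    x <- cbind(fs[, tr], ft[, tr])
    dom <- rep(c(0, 1), each = 150)
    st <- seizadapt:::adam_init(disc$params)
    for (it in 1:150) {
      fw <- seizadapt:::disc_forward(disc, x)
      dz <- (fw$prob - dom) / length(dom)
      gr <- seizadapt:::disc_backward(disc, fw, dz)$grads
      up <- seizadapt:::adam_step(disc$params, gr, st, lr = 0.01)
      disc$params <- up$params
      st <- up$state
    }
    held <- cbind(fs[, te], ft[, te])
    mean((seizadapt:::disc_forward(disc, held)$prob >= 0.5) == (dom == 1))
  }
  expect_gt(train_probe(delta = 1.5, seed = 1), 0.9)
  accs <- vapply(1:3, function(s) train_probe(delta = 0, seed = s), 0)
  expect_lt(abs(median(accs) - 0.5), 0.12)
})

test_that("empty domain sides are rejected", {
  x <- array(0, c(2, 16, 3))
  e <- array(0, c(2, 16, 0))
  expect_seiz_error(domain_batch(x, c(0, 1, 0), e), "non-empty")
  expect_seiz_error(domain_batch(e, integer(0), x), "non-empty")
})
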