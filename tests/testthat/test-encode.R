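test_that("the auto-encoder is built to the configured geometry", {
  cfg <- ae_config()
  expect_equal(cfg$latent_dim, 32L)
  model <- build_autoencoder(ae_config(latent_dim = 32, s = 32,
                                       channels = c(4, 8, 16), hidden = 16,
                                       seed = 3))
  z <- encode_ttc(model, banded_ttc(32, tau = 5))
  expect_length(z, 32)
  expect_true(all(is.finite(z)))
  rec <- decode_latent(model, z)
  expect_equal(dim(rec), c(32, 32))

  # identical seeds give identical initial parameters; different seeds differ
  m2 <- build_autoencoder(ae_config(latent_dim = 32, s = 32,
                                    channels = c(4, 8, 16), hidden = 16,
                                    seed = 3))
  expect_identical(model$params, m2$params)
  m3 <- build_autoencoder(ae_config(latent_dim = 32, s = 32,
                                    channels = c(4, 8, 16), hidden = 16,
                                    seed = 4))
  expect_false(identical(model$params, m3$params))

  expect_error(ae_config(latent_dim = 1), class = "specklematch_config_error")
  expect_error(ae_config(s = 20), class = "specklematch_config_error")
  expect_error(encode_ttc(model, banded_ttc(16, 3)),
               class = "specklematch_shape_error")
  expect_error(decode_latent(model, rep(0, 7)),
               class = "specklematch_shape_error")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- ae_config(latent_dim = 3, channels = c(2, 3, 4), hidden = 5,
                   s = 16, seed = 5)
  model <- build_autoencoder(cfg)
  # move biases off zero so no ReLU pre-activation sits exactly on a kink
  set.seed(17)
  for (nm in grep("_b$", names(model$params), value = TRUE)) {
    model$params[[nm]] <- rnorm(length(model$params[[nm]]), sd = 0.1)
  }
  n <- 3
  x <- matrix(rnorm(16 * 16 * n), 16 * 16, n)
  g <- specklematch:::ae_grad(model, x, n)
  h <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    ii <- seq_along(p)
    if (length(p) > 10) ii <- sample(length(p), 10)
    for (i in ii) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + h
      lp <- specklematch:::ae_grad(m2, x, n)$loss
      m2$params[[nm]][i] <- p[i] - h
      lm <- specklematch:::ae_grad(m2, x, n)$loss
      fd <- (lp - lm) / (2 * h)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("batched and single encodings agree and are deterministic", {
  fit <- cached_trained_ae()
  ttcs <- fit$ttcs[1:6]
  zb <- encode_ttc(fit$model, ttcs)
  expect_equal(dim(zb), c(6, 8))
  for (i in c(1, 4, 6)) {
    expect_equal(encode_ttc(fit$model, ttcs[[i]]), zb[i, ],
                 tolerance = 1e-6)
  }
  expect_identical(encode_ttc(fit$model, ttcs[[2]]),
                   encode_ttc(fit$model, ttcs[[2]]))
})

test_that("training is deterministic and reduces the loss", {
  cfg <- ae_config(latent_dim = 6, channels = c(3, 6, 12), hidden = 12,
                   s = 16, epochs = 10, batch_size = 16, lr = 2e-3, seed = 7)
  ttcs <- banded_ttc_set(48, 16, seed = 5)
  f1 <- ae_train(build_autoencoder(cfg), ttcs)
  f2 <- ae_train(build_autoencoder(cfg), ttcs)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history[length(f1$history)], f1$history[1])
  expect_error(ae_train(build_autoencoder(cfg), ttcs[1:4]),
               class = "specklematch_input_error")
})

test_that("a 200-map training run halves the reconstruction loss", {
  cfg <- ae_config(latent_dim = 8, channels = c(4, 8, 16), hidden = 16,
                   s = 16, epochs = 50, batch_size = 32, lr = 2e-3, seed = 13)
  ttcs <- banded_ttc_set(200, 16, tau_range = c(1.5, 10), noise = 0.02,
                         seed = 31)
  fit <- ae_train(build_autoencoder(cfg), ttcs)
  expect_lt(fit$history[length(fit$history)] / fit$history[1], 0.5)
  # loss history trends down: median of last 10 below median of first 10
  expect_lt(median(tail(fit$history, 10)), median(head(fit$history, 10)))
})

test_that("the network can overfit a single map to high precision", {
  cfg <- ae_config(latent_dim = 8, channels = c(4, 8, 16), hidden = 16,
                   s = 16, epochs = 500, batch_size = 1, lr = 3e-3, seed = 2)
  one <- banded_ttc(16, tau = 4)
  fit <- ae_train(build_autoencoder(cfg), list(one), min_inputs = 1)
  expect_lt(fit$history[length(fit$history)], 1e-3)
})

test_that("the trained encoder denoises and captures band structure", {
  fit <- cached_trained_ae()
  model <- fit$model
  # denoising: the reconstruction of a noisy map is closer to the clean
  # map than the noisy input itself, for most maps
  set.seed(41)
  taus <- runif(20, 2, 9)
  wins <- vapply(seq_along(taus), function(i) {
    clean <- banded_ttc(16, taus[i])
    noisy <- banded_ttc(16, taus[i], noise = 0.1, seed = 100 + i)
    rec <- reconstruct_ttc(model, noisy)
    mean((rec - clean$values)^2) < mean((noisy$values - clean$values)^2)
  }, logical(1))
  expect_gte(mean(wins), 0.7)

  # structure, not pixel statistics: held-out maps reconstruct better than
  # pixel-permuted controls
  set.seed(43)
  err <- function(x) {
    pre <- banded_ttc(16, 1)
    pre$values <- x
    mean((reconstruct_ttc(model, pre) - x)^2)
  }
  held <- banded_ttc(16, tau = 6.3, noise = 0.02, seed = 77)$values
  perm <- matrix(sample(held), 16, 16)
  expect_lt(err(held), err(perm))
})

test_that("latents vary smoothly along a graded family of maps", {
  fit <- cached_trained_ae()
  # a 'ring series': maps whose correlation time shrinks gradually, as TTCs
  # do with increasing q
  taus <- seq(8, 2, length.out = 10)
  z <- encode_ttc(fit$model, lapply(taus, function(t) banded_ttc(16, t)))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  adj <- vapply(1:9, function(i) cosine(z[i, ], z[i + 1, ]), numeric(1))
  set.seed(3)
  rnd <- replicate(200, {
    ij <- sample(10, 2)
    cosine(z[ij[1], ], z[ij[2], ])
  })
  expect_gt(mean(adj), mean(rnd))
})
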