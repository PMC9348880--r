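test_that("the mean normalized dot product behaves like a cosine average", {
  set.seed(2)
  z <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(objective_D(z, z), 1, tolerance = 1e-12)

  a <- rbind(c(1, 0, 0), c(0, 1, 0))
  b <- rbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(objective_D(a, b), 0)

  # cosines 1 and 0 average to 0.5
  a2 <- rbind(c(1, 0), c(1, 0))
  b2 <- rbind(c(2, 0), c(0, 3))
  expect_equal(objective_D(a2, b2), 0.5)

  # invariant to positive rescaling of any vector
  scl <- diag(runif(5, 0.1, 10))
  expect_equal(objective_D(scl %*% z, z), 1, tolerance = 1e-12)

  z0 <- z; z0[3, ] <- 0
  expect_error(objective_D(z0, z), class = "specklematch_degenerate_error")
})

test_that("differential evolution finds the optimum of a sphere function", {
  fn <- function(x) sum((x - 0.3)^2)
  fit <- de_optimize(fn, lower = rep(0, 5), upper = rep(1, 5),
                     max_iter = 300, seed = 4)
  expect_true(all(abs(fit$par - 0.3) < 1e-4))
  # best-so-far is non-increasing
  expect_true(all(diff(fit$history) <= 0))
  expect_identical(fit$n_evals, 15L * 5L * 301L)
})

test_that("differential evolution respects box constraints at every evaluation", {
  seen <- new.env(); seen$bad <- 0L
  fn <- function(x) {
    if (any(x < -1 - 1e-12) || any(x > 2 + 1e-12)) seen$bad <- seen$bad + 1L
    sum(x^2)
  }
  fit <- de_optimize(fn, lower = rep(-1, 3), upper = rep(2, 3),
                     pop_size = 12, max_iter = 50, seed = 1)
  expect_identical(seen$bad, 0L)
  expect_true(all(fit$population >= -1 & fit$population <= 2))
  expect_error(de_optimize(fn, lower = c(0, 0), upper = c(1, -1)),
               class = "specklematch_config_error")
  # determinism
  fit2 <- de_optimize(function(x) sum(x^2), rep(-1, 3), rep(2, 3),
                      pop_size = 12, max_iter = 30, seed = 9)
  fit3 <- de_optimize(function(x) sum(x^2), rep(-1, 3), rep(2, 3),
                      pop_size = 12, max_iter = 30, seed = 9)
  expect_identical(fit2$par, fit3$par)
})

test_that("latent lookup matches a brute-force nearest-neighbour scan", {
  table <- synthetic_latent_table(n_samples = 100, rings = 4:9, d = 6,
                                  seed = 8)
  se <- diff(range(table$eps)); sp <- diff(range(table$psi_gel))
  set.seed(14)
  for (i in 1:20) {
    eps <- runif(1, 0.4, 0.9); psi <- runif(1, 0.55, 1)
    d2 <- ((table$eps - eps) / se)^2 + ((table$psi_gel - psi) / sp)^2
    best <- which.min(d2)
    got <- sim_latent_lookup(table, eps, psi, q_um = 6 * 0.5, c_q = 0.5, k = 1)
    expect_equal(got, table$z[best, 3, ])  # ring 6 is the 3rd knot
  }
  # doubling c_q halves the queried ring coordinate
  z1 <- sim_latent_lookup(table, 0.7, 0.8, q_um = 4, c_q = 0.5, k = 1)
  z2 <- sim_latent_lookup(table, 0.7, 0.8, q_um = 8, c_q = 1.0, k = 1)
  expect_identical(z1, z2)
  expect_error(sim_latent_lookup(table, 0.7, 0.8, q_um = 20, c_q = 0.5),
               class = "specklematch_range_error")
})

test_that("ring interpolation is exact at knots, linear between them", {
  table <- synthetic_latent_table(n_samples = 5, rings = c(4, 6, 8), d = 4,
                                  seed = 3)
  i <- 2
  expect_equal(interpolate_latent(table, table$eps[i], table$psi_gel[i], 6),
               table$z[i, 2, ])
  mid <- interpolate_latent(table, table$eps[i], table$psi_gel[i], 7)
  expect_equal(mid, (table$z[i, 2, ] + table$z[i, 3, ]) / 2)

  # continuity: jumps along a fine sweep never exceed the inter-knot jump
  qs <- seq(4, 8, by = 0.05)
  zs <- sapply(qs, function(q) {
    interpolate_latent(table, table$eps[i], table$psi_gel[i], q)
  })
  max_step <- max(abs(zs[, -1] - zs[, -ncol(zs)]))
  knot_step <- max(abs(table$z[i, 2, ] - table$z[i, 1, ]),
                   abs(table$z[i, 3, ] - table$z[i, 2, ]))
  expect_lt(max_step, knot_step)
  expect_error(interpolate_latent(table, table$eps[i], table$psi_gel[i], 9.5),
               class = "specklematch_range_error")
})

test_that("experimental sets assemble one TTC per condition and Q", {
  mk <- function(cond, q) {
    specklematch:::new_ttc_map(matrix(1, 4, 4), 1:4, rep(1, 4),
                               q_center = NA, dq = NA, source = "fixture")
  }
  ds <- list(
    ttcs = c(lapply(1:5, function(q) mk(1, q)),
             lapply(1:5, function(q) mk(2, q))),
    meta = tibble::tibble(condition = rep(1:2, each = 5),
                          q_um = rep(seq(7.02, 8.2, length.out = 5), 2))
  )
  out <- assemble_experimental_set(ds)
  expect_length(out$ttcs, 10)
  expect_equal(out$meta$condition, rep(1:2, each = 5))

  one <- assemble_experimental_set(list(ttcs = ds$ttcs[1],
                                        meta = ds$meta[1, ]))
  expect_length(one$ttcs, 1)

  expect_error(assemble_experimental_set(ds, q_values = c(7.02, 7.02)),
               class = "specklematch_input_error")
  expect_error(assemble_experimental_set(ds, q_values = c(7.02, 9.99)),
               class = "specklematch_input_error")
})

test_that("the monotone chain programme matches brute-force enumeration", {
  set.seed(6)
  for (rep in 1:20) {
    n_c <- sample(2:4, 1)
    n_s <- sample(4:7, 1)
    eps <- round(runif(n_s, 0.4, 0.9), 2)  # duplicates possible
    score <- matrix(rnorm(n_c * n_s), n_c, n_s)
    got <- specklematch:::monotone_best_chain(score, eps)
    # brute force over all sample chains with non-increasing eps
    grids <- rep(list(seq_len(n_s)), n_c)
    combos <- as.matrix(expand.grid(grids))
    ok <- apply(combos, 1, function(ch) all(diff(eps[ch]) <= 1e-12))
    vals <- apply(combos, 1, function(ch) {
      sum(score[cbind(seq_len(n_c), ch)])
    })
    best_val <- max(vals[ok])
    expect_true(all(diff(eps[got]) <= 1e-12))
    expect_equal(sum(score[cbind(seq_len(n_c), got)]), best_val,
                 tolerance = 1e-12)
  }
})
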