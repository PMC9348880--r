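#' Auto-encoder configuration
#'
#' Hyper-parameters of the convolutional auto-encoder that compresses
#' preprocessed TTC maps into latent vectors. The encoder applies three
#' stride-2 3x3 convolutional stages, global average pooling to one value
#' per channel, and a two-layer fully connected head ending in the
#' \code{latent_dim}-dimensional code (default 32). The decoder mirrors
#' it: a dense layer expands the code to an \code{s/8 x s/8} feature
#' stack, followed by three (nearest-neighbour upsample + 3x3 convolution)
#' stages back to \code{s x s}. Training minimises reconstruction mean
#' squared error.
#'
#' @param latent_dim Latent dimensionality (default 32).
#' @param channels Integer vector of the three encoder channel widths.
#' @param hidden Width of the fully connected hidden layer after pooling.
#' @param pool_out Side length of the adaptive average pooling output (1 =
#'   global pooling; 2 keeps a coarse 2x2 position grid per channel, which
#'   preserves where along the diagonal a feature sits -- the ageing
#'   information of a TTC).
#' @param s Input side length; must be divisible by 8.
#' @param epochs,batch_size,lr Training schedule (Adam optimiser).
#' @param seed RNG seed controlling initialisation and batch shuffling.
#' @return An \code{ae_config} object.
#' @export
ae_config <- function(latent_dim = 32, channels = c(16, 32, 64), hidden = 64,
                      pool_out = 2, s = 64, epochs = 100, batch_size = 64,
                      lr = 1e-3, seed = 1L) {
  if (latent_dim < 2) {
    stop(errorCondition("latent_dim must be >= 2",
                        class = "specklematch_config_error"))
  }
  if (length(channels) != 3 || any(channels < 1)) {
    stop(errorCondition("`channels` must give three positive widths",
                        class = "specklematch_config_error"))
  }
  if (s %% 8 != 0 || s < 16) {
    stop(errorCondition("input size `s` must be a multiple of 8 and >= 16",
                        class = "specklematch_config_error"))
  }
  g <- s %/% 8L
  if (pool_out < 1 || g %% pool_out != 0 ||
      bitwAnd(g %/% pool_out, g %/% pool_out - 1L) != 0) {
    stop(errorCondition(
      "`pool_out` must divide s/8 with a power-of-two quotient",
      class = "specklematch_config_error"))
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels), hidden = as.integer(hidden),
                 pool_out = as.integer(pool_out),
                 s = as.integer(s), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), input_shift = 1),
            class = "ae_config")
}

#' Build an (untrained) TTC auto-encoder
#'
#' Allocates seeded He-initialised parameters and the precomputed
#' convolution index tables for the architecture described in
#' \code{\link{ae_config}}. Two builds with the same configuration and
#' seed have identical initial parameters.
#'
#' @param config An \code{\link{ae_config}}.
#' @return An \code{ae_model}: list with \code{config}, \code{params} and
#'   \code{plans}; \code{n_params} records the parameter count.
#' @export
build_autoencoder <- function(config = ae_config()) {
  s <- config$s
  ch <- config$channels
  g <- s %/% 8L
  po <- config$pool_out
  pool_plans <- list()
  side <- g
  while (side > po) {
    side <- side %/% 2L
    pool_plans[[length(pool_plans) + 1]] <- make_up_plan(side)
  }
  plans <- list(
    e1 = make_conv_plan(s, stride = 2), # s -> s/2
    e2 = make_conv_plan(s %/% 2L, stride = 2),
    e3 = make_conv_plan(s %/% 4L, stride = 2),
    pool = pool_plans,
    u1 = make_up_plan(g), d1 = make_conv_plan(2L * g, stride = 1),
    u2 = make_up_plan(2L * g), d2 = make_conv_plan(4L * g, stride = 1),
    u3 = make_up_plan(4L * g), d3 = make_conv_plan(s, stride = 1)
  )
  kk <- 9L
  params <- withr_seed(config$seed, list(
    ec1_w = he_init(kk * 1, ch[1]), ec1_b = numeric(ch[1]),
    ec2_w = he_init(kk * ch[1], ch[2]), ec2_b = numeric(ch[2]),
    ec3_w = he_init(kk * ch[2], ch[3]), ec3_b = numeric(ch[3]),
    ef1_w = he_init(ch[3] * config$pool_out^2, config$hidden),
    ef1_b = numeric(config$hidden),
    ef2_w = he_init(config$hidden, config$latent_dim, gain = 1),
    ef2_b = numeric(config$latent_dim),
    df_w = he_init(config$latent_dim, ch[3] * g * g),
    df_b = numeric(ch[3] * g * g),
    dc3_w = he_init(kk * ch[3], ch[2]), dc3_b = numeric(ch[2]),
    dc2_w = he_init(kk * ch[2], ch[1]), dc2_b = numeric(ch[1]),
    dc1_w = he_init(kk * ch[1], 1, gain = 1), dc1_b = numeric(1)
  ))
  structure(list(config = config, params = params, plans = plans, g = g,
                 n_params = sum(vapply(params, length, integer(1))),
                 trained = FALSE),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model> input %dx%d -> latent %d (%s), %d parameters%s\n",
              x$config$s, x$config$s, x$config$latent_dim,
              paste(x$config$channels, collapse = "-"), x$n_params,
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}

# Encoder forward pass. x: plane matrix (s^2, n). Returns latent (n, d)
# plus caches when `keep` is TRUE.
enc_forward <- function(model, x, n, keep = FALSE) {
  p <- model$params
  pl <- model$plans
  ch <- model$config$channels
  if (ncol(x) != 1) x <- matrix(as.vector(x), ncol = 1)
  c1 <- conv_forward(x, p$ec1_w, p$ec1_b, pl$e1, 1L, ch[1], n)
  a1 <- relu(c1$out)
  c2 <- conv_forward(a1, p$ec2_w, p$ec2_b, pl$e2, ch[1], ch[2], n)
  a2 <- relu(c2$out)
  c3 <- conv_forward(a2, p$ec3_w, p$ec3_b, pl$e3, ch[2], ch[3], n)
  a3 <- relu(c3$out)
  po <- model$config$pool_out
  pp <- a3
  for (plan in pl$pool) pp <- pool2_forward(pp, plan, n)
  # (po^2 * n) x ch3 plane -> (n, ch3 * po^2), pixel fastest within channel
  pooled <- matrix(aperm(array(pp, c(po * po, n, ch[3])), c(2, 3, 1)),
                   n, ch[3] * po * po)
  h_pre <- sweep(pooled %*% p$ef1_w, 2, p$ef1_b, `+`)
  h <- relu(h_pre)
  z <- sweep(h %*% p$ef2_w, 2, p$ef2_b, `+`)
  out <- list(z = z)
  if (keep) {
    out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                      pooled = pooled, h = h)
  }
  out
}

dec_forward <- function(model, z, n, keep = FALSE) {
  p <- model$params
  pl <- model$plans
  ch <- model$config$channels
  g <- model$g
  f_pre <- sweep(z %*% p$df_w, 2, p$df_b, `+`)
  f <- relu(f_pre)
  # f rows are samples, entries pixel-fastest within channel; rearrange to
  # the sample-major plane layout (g^2 * n) x ch3
  q3 <- matrix(aperm(array(t(f), c(g * g, ch[3], n)), c(1, 3, 2)),
               g * g * n, ch[3])
  u1 <- up_forward(q3, pl$u1, n)
  d3 <- conv_forward(u1, p$dc3_w, p$dc3_b, pl$d1, ch[3], ch[2], n)
  b3 <- relu(d3$out)
  u2 <- up_forward(b3, pl$u2, n)
  d2 <- conv_forward(u2, p$dc2_w, p$dc2_b, pl$d2, ch[2], ch[1], n)
  b2 <- relu(d2$out)
  u3 <- up_forward(b2, pl$u3, n)
  d1 <- conv_forward(u3, p$dc1_w, p$dc1_b, pl$d3, ch[1], 1L, n)
  out <- list(xhat = d1$out)
  if (keep) {
    out$cache <- list(f = f, q3 = q3, u1 = u1, d3 = d3, b3 = b3, u2 = u2,
                      d2 = d2, b2 = b2, u3 = u3, d1 = d1)
  }
  out
}

# Full forward + backward for one batch; returns loss and gradients.
ae_grad <- function(model, x, n) {
  p <- model$params
  pl <- model$plans
  ch <- model$config$channels
  g <- model$g
  if (ncol(x) != 1) x <- matrix(as.vector(x), ncol = 1)
  enc <- enc_forward(model, x, n, keep = TRUE)
  dec <- dec_forward(model, enc$z, n, keep = TRUE)
  ec <- enc$cache
  dc <- dec$cache
  resid <- dec$xhat - x
  loss <- mean(resid^2)
  grads <- list()
  dxhat <- 2 * resid / length(resid)

  bd1 <- conv_backward(dxhat, dc$d1$m, p$dc1_w, pl$d3, ch[1], 1L, n)
  grads$dc1_w <- bd1$dw; grads$dc1_b <- bd1$db
  du3 <- up_backward(bd1$dp, pl$u3, n)
  du3[dc$b2 <= 0] <- 0
  bd2 <- conv_backward(du3, dc$d2$m, p$dc2_w, pl$d2, ch[2], ch[1], n)
  grads$dc2_w <- bd2$dw; grads$dc2_b <- bd2$db
  du2 <- up_backward(bd2$dp, pl$u2, n)
  du2[dc$b3 <= 0] <- 0
  bd3 <- conv_backward(du2, dc$d3$m, p$dc3_w, pl$d1, ch[3], ch[2], n)
  grads$dc3_w <- bd3$dw; grads$dc3_b <- bd3$db
  dq3 <- up_backward(bd3$dp, pl$u1, n)
  # back to (n, ch3*g^2), pixel-fastest within channel
  df <- t(matrix(aperm(array(dq3, c(g * g, n, ch[3])), c(1, 3, 2)),
                 g * g * ch[3], n))
  df[dc$f <= 0] <- 0
  grads$df_w <- crossprod(enc$z, df); grads$df_b <- colSums(df)
  dz <- tcrossprod(df, p$df_w)

  grads$ef2_w <- crossprod(ec$h, dz); grads$ef2_b <- colSums(dz)
  dh <- tcrossprod(dz, p$ef2_w)
  dh[ec$h <= 0] <- 0
  grads$ef1_w <- crossprod(ec$pooled, dh); grads$ef1_b <- colSums(dh)
  dpool <- tcrossprod(dh, p$ef1_w)
  po <- model$config$pool_out
  dpp <- matrix(aperm(array(dpool, c(n, ch[3], po * po)), c(3, 1, 2)),
                po * po * n, ch[3])
  for (plan in rev(pl$pool)) dpp <- pool2_backward(dpp, plan, n)
  da3 <- dpp
  da3[ec$a3 <= 0] <- 0
  be3 <- conv_backward(da3, ec$c3$m, p$ec3_w, pl$e3, ch[2], ch[3], n)
  grads$ec3_w <- be3$dw; grads$ec3_b <- be3$db
  da2 <- be3$dp
  da2[ec$a2 <= 0] <- 0
  be2 <- conv_backward(da2, ec$c2$m, p$ec2_w, pl$e2, ch[1], ch[2], n)
  grads$ec2_w <- be2$dw; grads$ec2_b <- be2$db
  da1 <- be2$dp
  da1[ec$a1 <= 0] <- 0
  be1 <- conv_backward(da1, ec$c1$m, p$ec1_w, pl$e1, 1L, ch[1], n)
  grads$ec1_w <- be1$dw; grads$ec1_b <- be1$db

  list(loss = loss, grads = grads)
}

ttcs_to_planes <- function(ttcs, config) {
  s <- config$s
  if (inherits(ttcs, "preprocessed_ttc")) ttcs <- list(ttcs)
  bad <- vapply(ttcs, function(t) t$s != s, logical(1))
  if (any(bad)) {
    stop(errorCondition(
      sprintf("TTC size does not match the model input size %d", s),
      class = "specklematch_shape_error"))
  }
  vapply(ttcs, function(t) as.vector(t$values) - config$input_shift,
         numeric(s * s))
}

#' Train the auto-encoder on preprocessed TTCs
#'
#' Minimises reconstruction mean squared error with Adam over shuffled
#' minibatches. Training is deterministic for a given model seed and data
#' order: the same call twice yields identical loss histories.
#'
#' @param model An \code{ae_model} from \code{\link{build_autoencoder}}.
#' @param ttcs List of \code{preprocessed_ttc} of the model's input size.
#' @param epochs,batch_size,lr Optional overrides of the config values.
#' @param min_inputs Minimum training-set size (sanity guard; lower it for
#'   single-map overfitting experiments).
#' @param verbose Print the epoch loss while training.
#' @return List with the trained \code{model} and the per-epoch
#'   \code{history} of mean training loss.
#' @export
ae_train <- function(model, ttcs, epochs = NULL, batch_size = NULL, lr = NULL,
                     min_inputs = 32, verbose = FALSE) {
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(lr)) cfg$lr else lr
  x_all <- ttcs_to_planes(ttcs, cfg)
  n_all <- ncol(x_all)
  if (n_all < min_inputs) {
    stop(errorCondition(
      sprintf("need at least %d training TTCs, got %d", min_inputs, n_all),
      class = "specklematch_input_error"))
  }
  params <- model$params
  state <- adam_init(params)
  history <- numeric(epochs)
  withr_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_all)
      starts <- seq(1, n_all, by = batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        take <- ord[s0:min(s0 + batch_size - 1, n_all)]
        xb <- x_all[, take, drop = FALSE]
        model$params <- params
        gb <- ae_grad(model, xb, length(take))
        if (!is.finite(gb$loss)) {
          stop(errorCondition("training diverged (non-finite loss)",
                              class = "specklematch_training_error"))
        }
        upd <- adam_update(params, gb$grads, state, lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + gb$loss * length(take)
      }
      history[ep] <- ep_loss / n_all
      if (verbose) cat(sprintf("epoch %3d  loss %.6f\n", ep, history[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Encode TTC maps into latent vectors
#'
#' Runs the encoder half of the auto-encoder. Batched and single calls
#' agree to numerical precision.
#'
#' @param model An \code{ae_model}.
#' @param ttcs A \code{preprocessed_ttc} or a list of them.
#' @return For a single map, a numeric latent vector; for a list, a matrix
#'   with one row per map.
#' @export
encode_ttc <- function(model, ttcs) {
  single <- inherits(ttcs, "preprocessed_ttc")
  x <- ttcs_to_planes(ttcs, model$config)
  z <- enc_forward(model, x, ncol(x))$z
  if (single) drop(z) else z
}

#' Decode a latent vector back to a TTC map
#'
#' @param model An \code{ae_model}.
#' @param z Latent vector (length \code{latent_dim}) or matrix of rows.
#' @return A reconstructed \code{s x s} matrix (single vector input) or a
#'   list of matrices.
#' @export
decode_latent <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != model$config$latent_dim) {
    stop(errorCondition("latent dimensionality does not match the model",
                        class = "specklematch_shape_error"))
  }
  n <- nrow(z)
  planes <- dec_forward(model, z, n)$xhat   # (s^2 * n) x 1, sample-major
  s <- model$config$s
  mats <- lapply(seq_len(n), function(i) {
    matrix(planes[(i - 1) * s * s + seq_len(s * s), 1], s, s) +
      model$config$input_shift
  })
  if (n == 1) mats[[1]] else mats
}

#' Auto-encoder reconstruction of a TTC map
#'
#' @param model An \code{ae_model}.
#' @param ttc A \code{preprocessed_ttc}.
#' @return The reconstructed \code{s x s} matrix.
#' @export
reconstruct_ttc <- function(model, ttc) {
  decode_latent(model, encode_ttc(model, ttc))
}

#' Latent table of a simulation library
#'
#' Encodes every (parameter pair, ring) entry of a TTC library into its
#' latent vector, producing the lookup structure used by the matcher.
#'
#' @param model A trained \code{ae_model}.
#' @param library A \code{ttc_library} from
#'   \code{\link{simulate_ttc_library}}.
#' @return A \code{latent_table}: list with \code{eps}, \code{psi_gel}
#'   (length \code{n_samples}), \code{rings}, and \code{z} (array
#'   \code{n_samples x n_rings x latent_dim}).
#' @export
build_latent_table <- function(model, library) {
  n_s <- nrow(library$params)
  rings <- library$rings
  d <- model$config$latent_dim
  z <- array(NA_real_, c(n_s, length(rings), d))
  for (i in seq_len(n_s)) {
    zi <- encode_ttc(model, library$ttcs[[i]])
    z[i, , ] <- zi
  }
  structure(list(eps = library$params$eps, psi_gel = library$params$psi_gel,
                 rings = rings, z = z, latent_dim = d),
            class = "latent_table")
}

#' @export
print.latent_table <- function(x, ...) {
  cat(sprintf("<latent_table> %d parameter samples x %d rings x %d latent dims\n",
              length(x$eps), length(x$rings), x$latent_dim))
  cat(sprintf("  eps in [%.3g, %.3g], psi_gel in [%.3g, %.3g], rings %g..%g\n",
              min(x$eps), max(x$eps), min(x$psi_gel), max(x$psi_gel),
              min(x$rings), max(x$rings)))
  invisible(x)
}

# Nearest parameter samples in normalised (eps, psi_gel) space.
nearest_samples <- function(table, eps, psi_gel, k = 1) {
  se <- diff(range(table$eps))
  sp <- diff(range(table$psi_gel))
  if (se == 0) se <- 1
  if (sp == 0) sp <- 1
  d2 <- ((table$eps - eps) / se)^2 + ((table$psi_gel - psi_gel) / sp)^2
  ord <- order(d2)[seq_len(min(k, length(d2)))]
  list(idx = ord, d2 = d2[ord])
}

# Piecewise-linear interpolation of one sample's latents across the ring axis.
ring_interp <- function(table, sample_idx, q) {
  rings <- table$rings
  if (q < min(rings) - 1e-9 || q > max(rings) + 1e-9) {
    stop(errorCondition(
      sprintf("q = %g outside the ring grid [%g, %g]; extrapolation refused",
              q, min(rings), max(rings)),
      class = "specklematch_range_error"))
  }
  q <- min(max(q, min(rings)), max(rings))
  hi <- findInterval(q, rings, rightmost.closed = TRUE) + 1L
  hi <- min(max(hi, 2L), length(rings))
  lo <- hi - 1L
  w <- (q - rings[lo]) / (rings[hi] - rings[lo])
  (1 - w) * table$z[sample_idx, lo, ] + w * table$z[sample_idx, hi, ]
}

#' Interpolate a latent vector across the ring axis
#'
#' Because the latent components vary continuously with the ring radius, a
#' TTC at an arbitrary radius between the stored rings can be represented
#' by per-component piecewise-linear interpolation. The parameter pair is
#' resolved to its nearest stored sample first.
#'
#' @param table A \code{latent_table}.
#' @param eps,psi_gel Query parameter pair.
#' @param q Fractional ring coordinate, inside the stored ring range.
#' @return Numeric latent vector.
#' @export
interpolate_latent <- function(table, eps, psi_gel, q) {
  nn <- nearest_samples(table, eps, psi_gel, k = 1)
  ring_interp(table, nn$idx[1], q)
}
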