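#' Mean normalized dot product between latent sets
#'
#' The matching objective: the average cosine similarity
#' \deqn{D = \frac{1}{N}\sum_j
#'   \frac{z^{exp}_j}{\|z^{exp}_j\|}\cdot\frac{z^{sim}_j}{\|z^{sim}_j\|}}
#' between paired experimental and simulated latent vectors. Lies in
#' \code{[-1, 1]}; invariant to positive rescaling of any vector.
#'
#' @param exp_latents,sim_latents Matrices with one latent vector per row
#'   (or lists of vectors), equal length, matching order.
#' @return Scalar \code{D}.
#' @export
objective_D <- function(exp_latents, sim_latents) {
  ze <- as_latent_matrix(exp_latents)
  zs <- as_latent_matrix(sim_latents)
  stopifnot(nrow(ze) == nrow(zs), ncol(ze) == ncol(zs))
  ne <- sqrt(rowSums(ze^2))
  ns <- sqrt(rowSums(zs^2))
  if (any(ne == 0) || any(ns == 0)) {
    stop(errorCondition("zero-norm latent vector",
                        class = "specklematch_degenerate_error"))
  }
  mean(rowSums(ze * zs) / (ne * ns))
}

as_latent_matrix <- function(z) {
  if (is.list(z)) z <- do.call(rbind, z)
  if (is.null(dim(z))) z <- matrix(z, 1)
  z
}

#' Look up a simulated latent vector for continuous query parameters
#'
#' Maps an experimental Q value to simulation ring units through the
#' calibration factor (\code{q_sim = q_um / c_q}), selects training
#' samples near the queried \code{(eps, psi_gel)} in normalised parameter
#' space, and interpolates each sample's latents linearly across the ring
#' axis. With \code{k = 1} this is plain nearest-neighbour selection; with
#' \code{k > 1} the neighbours are blended by inverse squared distance,
#' which makes the matching objective continuous in the physical
#' parameters.
#'
#' @param table A \code{latent_table}.
#' @param eps,psi_gel Query parameters.
#' @param q_um Experimental Q value (inverse micrometres).
#' @param c_q Calibration factor, \code{Q_um = c_q * q_pixel}.
#' @param k Number of parameter-space neighbours to blend.
#' @return Numeric latent vector.
#' @export
sim_latent_lookup <- function(table, eps, psi_gel, q_um, c_q, k = 1) {
  q <- q_um / c_q
  nn <- nearest_samples(table, eps, psi_gel, k = k)
  if (length(nn$idx) == 1 || k == 1) {
    return(ring_interp(table, nn$idx[1], q))
  }
  w <- 1 / (nn$d2 + 1e-12)
  w <- w / sum(w)
  z <- 0
  for (j in seq_along(nn$idx)) {
    z <- z + w[j] * ring_interp(table, nn$idx[j], q)
  }
  z
}

#' Differential evolution over a box
#'
#' Classic rand/1/bin differential evolution minimising \code{fn} over
#' box constraints, with candidates clipped to the bounds. Deterministic
#' for a given seed. The best objective value is non-increasing across
#' generations by construction (greedy selection).
#'
#' @param fn Objective to minimise; receives a numeric parameter vector.
#' @param lower,upper Bound vectors of equal length.
#' @param pop_size Population size (default \code{15 * dim}).
#' @param f_weight Differential weight F (default 0.7).
#' @param cr Crossover probability (default 0.9).
#' @param max_iter Number of generations (production default 1500).
#' @param seed RNG seed.
#' @return List with \code{par}, \code{value}, \code{history} (best value
#'   per generation), \code{n_evals} and \code{population}.
#' @export
de_optimize <- function(fn, lower, upper, pop_size = NULL, f_weight = 0.7,
                        cr = 0.9, max_iter = 1500, seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d)
  if (any(upper <= lower)) {
    stop(errorCondition("infeasible bounds: need upper > lower",
                        class = "specklematch_config_error"))
  }
  if (is.null(pop_size)) pop_size <- 15L * d
  pop_size <- max(4L, as.integer(pop_size))
  span <- upper - lower
  withr_seed(seed, {
    pop <- matrix(stats::runif(pop_size * d), pop_size, d)
    pop <- sweep(sweep(pop, 2, span, `*`), 2, lower, `+`)
    vals <- apply(pop, 1, fn)
    n_evals <- pop_size
    history <- numeric(max_iter)
    for (gen in seq_len(max_iter)) {
      for (i in seq_len(pop_size)) {
        idx <- sample.int(pop_size, 3)
        while (any(idx == i)) idx <- sample.int(pop_size, 3)
        mutant <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
        cross <- stats::runif(d) < cr
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        v <- fn(trial)
        n_evals <- n_evals + 1L
        if (v <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- v
        }
      }
      history[gen] <- min(vals)
    }
    best <- which.min(vals)
    list(par = pop[best, ], value = vals[best], history = history,
         n_evals = n_evals, population = pop)
  })
}

#' Match pseudo-experimental TTCs to the simulation library
#'
#' Fits, by differential evolution, one \code{(eps, psi_gel)} pair per
#' quench condition plus three global calibration parameters: the crop
#' window \code{(t_start, t_end)} that maps the experimental time axis
#' onto the simulation timescale, and the Q conversion factor \code{c_q}.
#' The objective is the mean normalized dot product \code{D} between the
#' encoded experimental maps and ring-interpolated simulated latents; an
#' optional penalty enforces that the fitted quench depth is
#' non-increasing with quench temperature. Experimental maps are cropped,
#' visibility-normalized, downsampled and encoded once per distinct crop
#' window (rounded to the frame grid) and cached.
#'
#' @param dataset A \code{fixture_dataset} or compatible list with
#'   \code{ttcs}, \code{meta} (columns \code{condition}, \code{q_um}) and
#'   \code{times}. Conditions must be ordered by quench temperature.
#' @param table A \code{latent_table}.
#' @param model The trained \code{ae_model} used to encode the
#'   experimental maps.
#' @param q_values Q values used per condition (default: all present).
#' @param method \code{"profile"} (default): differential evolution runs
#'   over the three calibration parameters only, and within every
#'   evaluation the per-condition \code{(eps, psi_gel)} are chosen
#'   exactly by scoring all library samples, with the quench-temperature
#'   monotonicity imposed by dynamic programming. \code{"joint"}: one
#'   differential evolution over all parameters at once (physics
#'   parameters continuous, monotonicity as a penalty).
#' @param monotone_eps Apply the quench-temperature monotonicity
#'   constraint/penalty.
#' @param k_neighbors Parameter-space neighbours blended in the latent
#'   lookup.
#' @param bounds Optional list overriding any of \code{eps}, \code{psi_gel},
#'   \code{t_start}, \code{t_len}, \code{c_q} (each a length-2 range).
#' @param pop_size,f_weight,cr,max_iter,seed Differential-evolution
#'   settings (see \code{\link{de_optimize}}).
#' @param penalty_weight Weight of the monotonicity penalty.
#' @return A \code{match_result}: per-condition tibble of fitted
#'   parameters, calibration values, best \code{D}, optimisation history
#'   and provenance.
#' @export
match_ttcs <- function(dataset, table, model, q_values = NULL,
                       method = c("profile", "joint"),
                       monotone_eps = TRUE, k_neighbors = 4,
                       bounds = list(), pop_size = NULL, f_weight = 0.7,
                       cr = 0.9, max_iter = 1500, seed = 1L,
                       penalty_weight = 10) {
  method <- match.arg(method)
  set <- assemble_experimental_set(dataset, q_values)
  meta <- set$meta
  conditions <- sort(unique(meta$condition))
  n_c <- length(conditions)
  n_ttc <- length(set$ttcs)
  times <- dataset$times
  n_t <- length(times)
  s <- model$config$s
  period <- if (n_t > 1) times[2] - times[1] else 1

  # anchor the crop-window search at the observable ring-intensity peak:
  # the same physical marker (maximum of the ring intensity) that crops
  # the simulated maps. Without the anchor the window is nearly degenerate
  # with the physical parameters and the fit can wander into windows that
  # include the early homogeneous stage.
  peak_idx <- vapply(set$ttcs, function(ttc) {
    ri <- moving_average(ttc$ring_intensity, 5)
    which(ri >= 0.95 * max(ri))[1]
  }, integer(1))
  peak_times <- times[peak_idx]
  t_anchor <- stats::median(peak_times)
  span <- times[n_t] - times[1]
  b <- list(
    eps = range(table$eps),
    psi_gel = range(table$psi_gel),
    t_start = c(max(times[1], t_anchor - 0.1 * span),
                min(t_anchor + 0.1 * span, times[1] + 0.9 * span)),
    # the experiment outlasts the simulated coarsening, so the matched
    # window must span most of the post-onset record; short windows would
    # otherwise trade off almost freely against the Q calibration
    t_len = c(max((s + 2) * period, 0.75 * (span - t_anchor)), times[n_t]),
    c_q = c(max(meta$q_um) / max(table$rings), min(meta$q_um) / min(table$rings))
  )
  b[names(bounds)] <- bounds
  if (b$c_q[1] >= b$c_q[2]) {
    stop(errorCondition(
      "ring range too narrow for the requested Q values: empty c_q interval",
      class = "specklematch_config_error"))
  }

  lower <- c(rep(b$eps[1], n_c), rep(b$psi_gel[1], n_c),
             b$t_start[1], b$t_len[1], b$c_q[1])
  upper <- c(rep(b$eps[2], n_c), rep(b$psi_gel[2], n_c),
             b$t_start[2], b$t_len[2], b$c_q[2])

  cond_of <- match(meta$condition, conditions)
  cache <- new.env(parent = emptyenv())
  bad_value <- 2 + penalty_weight  # worse than any attainable -D
  # centre latents on the library mean: ReLU encoders produce codes with a
  # large shared positive component that would otherwise crowd all cosines
  # towards 1 and flatten the objective
  z_centre <- apply(table$z, 3, mean)

  # every experimental map is cropped at its own ring-intensity peak when
  # that lies inside the fitted window -- the same crop rule the library
  # maps receive -- so the global (t_start, t_end) acts as a window bound
  # and timescale anchor rather than overriding the per-ring alignment
  exp_latents_for <- function(t_start, t_len) {
    i0 <- min(max(1L, 1L + as.integer(round(t_start / period))), n_t - 1L)
    i1 <- min(n_t, max(i0 + 1L, 1L + as.integer(round((t_start + t_len) / period))))
    key <- paste0(i0, "_", i1)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch({
      pre <- lapply(seq_along(set$ttcs), function(j) {
        ttc <- set$ttcs[[j]]
        # cap like the library crop: keep at least s frames in the window
        j0 <- max(i0, min(peak_idx[j], i1 - s + 1L))
        j0 <- max(1L, min(j0, i1 - 1L))
        sub <- new_ttc_map(ttc$values[j0:i1, j0:i1, drop = FALSE],
                           ttc$times[j0:i1], ttc$ring_intensity[j0:i1],
                           ttc$q_center, ttc$dq, ttc$source, crop_index = j0)
        rescale_ttc(normalize_visibility(smooth_diagonal(sub)), s)
      })
      encode_ttc(model, pre)
    }, error = function(e) NULL)
    cache[[key]] <- if (is.null(res)) list(NULL) else res
    cache[[key]]
  }

  # ---- profile method: exact inner optimisation over library samples ----
  n_samp <- length(table$eps)
  d_lat <- table$latent_dim
  z_centre_m <- matrix(z_centre, 1)

  profile_eval <- function(t_start, t_len, c_q, keep = FALSE) {
    ze <- exp_latents_for(t_start, t_len)
    if (is.list(ze)) return(if (keep) NULL else bad_value)
    qs <- meta$q_um / c_q
    if (any(qs < min(table$rings)) || any(qs > max(table$rings))) {
      return(if (keep) NULL else bad_value)
    }
    ze_c <- sweep(ze, 2, z_centre)
    ze_n <- ze_c / sqrt(rowSums(ze_c^2))
    # cosine of every (map, sample) pair at the mapped ring coordinate
    cosm <- matrix(NA_real_, n_ttc, n_samp)
    for (si in seq_len(n_samp)) {
      zs <- t(vapply(qs, function(q) ring_interp(table, si, q),
                     numeric(d_lat)))
      zs_c <- sweep(zs, 2, z_centre)
      zs_n <- zs_c / sqrt(rowSums(zs_c^2))
      cosm[, si] <- rowSums(ze_n * zs_n)
    }
    score <- rowsum(cosm, cond_of) / as.vector(table(cond_of))  # n_c x n_samp
    if (monotone_eps && n_c > 1) {
      sel_samples <- monotone_best_chain(score, table$eps)
    } else {
      sel_samples <- apply(score, 1, which.max)
    }
    d_val <- mean(score[cbind(seq_len(n_c), sel_samples)])
    if (keep) {
      list(d = d_val, samples = sel_samples, score = score)
    } else {
      -d_val
    }
  }

  objective_profile <- function(par) {
    profile_eval(par[1], par[2], par[3])
  }

  objective <- function(par) {
    eps <- par[seq_len(n_c)]
    psi <- par[n_c + seq_len(n_c)]
    t_start <- par[2 * n_c + 1]
    t_len <- par[2 * n_c + 2]
    c_q <- par[2 * n_c + 3]
    ze <- exp_latents_for(t_start, t_len)
    if (is.list(ze)) return(bad_value)
    zs <- matrix(NA_real_, n_ttc, table$latent_dim)
    for (j in seq_len(n_ttc)) {
      ci <- cond_of[j]
      q <- meta$q_um[j] / c_q
      if (q < min(table$rings) || q > max(table$rings)) return(bad_value)
      zs[j, ] <- sim_latent_lookup(table, eps[ci], psi[ci], meta$q_um[j],
                                   c_q, k = k_neighbors)
    }
    ze_c <- sweep(ze, 2, z_centre)
    zs_c <- sweep(zs, 2, z_centre)
    if (any(rowSums(ze_c^2) == 0) || any(rowSums(zs_c^2) == 0)) {
      return(bad_value)
    }
    d_val <- objective_D(ze_c, zs_c)
    pen <- 0
    if (monotone_eps && n_c > 1) {
      pen <- penalty_weight * sum(pmax(0, diff(eps)))
    }
    -d_val + pen
  }

  if (method == "profile") {
    lower3 <- c(b$t_start[1], b$t_len[1], b$c_q[1])
    upper3 <- c(b$t_start[2], b$t_len[2], b$c_q[2])
    fit <- de_optimize(objective_profile, lower3, upper3,
                       pop_size = pop_size, f_weight = f_weight, cr = cr,
                       max_iter = max_iter, seed = seed)
    par <- fit$par
    prof <- profile_eval(par[1], par[2], par[3], keep = TRUE)
    calib <- list(t_start = par[1], t_end = par[1] + par[2], c_q = par[3])
    per_condition <- tibble::tibble(
      condition = conditions,
      eps = table$eps[prof$samples],
      psi_gel = table$psi_gel[prof$samples]
    )
  } else {
    fit <- de_optimize(objective, lower, upper, pop_size = pop_size,
                       f_weight = f_weight, cr = cr, max_iter = max_iter,
                       seed = seed)
    par <- fit$par
    calib <- list(t_start = par[2 * n_c + 1],
                  t_end = par[2 * n_c + 1] + par[2 * n_c + 2],
                  c_q = par[2 * n_c + 3])
    per_condition <- tibble::tibble(
      condition = conditions,
      eps = par[seq_len(n_c)],
      psi_gel = par[n_c + seq_len(n_c)]
    )
  }
  structure(list(
    per_condition = per_condition,
    calibration = calib,
    D = if (method == "profile") -fit$value else {
      -fit$value + if (monotone_eps && n_c > 1) {
        penalty_weight * sum(pmax(0, diff(per_condition$eps)))
      } else 0
    },
    objective_value = fit$value,
    history = -fit$history,
    n_evals = fit$n_evals,
    settings = list(method = method, monotone_eps = monotone_eps,
                    k_neighbors = k_neighbors,
                    bounds = b,
                    pop_size = if (is.null(pop_size)) 15L * length(lower) else pop_size,
                    f_weight = f_weight,
                    cr = cr, max_iter = max_iter, seed = seed,
                    penalty_weight = penalty_weight),
    q_values = sort(unique(meta$q_um))
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d conditions, D = %.4f (%d evaluations)\n",
              nrow(x$per_condition), x$D, x$n_evals))
  cat(sprintf("  calibration: t_start = %.3g, t_end = %.3g, c_q = %.4g\n",
              x$calibration$t_start, x$calibration$t_end, x$calibration$c_q))
  print(x$per_condition)
  invisible(x)
}

#' Per-map matching with averaged calibration
#'
#' The alternative fit topology: every TTC is fitted independently over
#' its own \code{(eps, psi_gel, t_start, t_end, c_q)}, and the calibration
#' parameters are averaged over all maps afterwards; per-condition
#' parameters are averaged over that condition's Q values. Slower but
#' exposes the scatter between maps.
#'
#' @inheritParams match_ttcs
#' @return A \code{match_result} whose \code{per_map} field holds the
#'   individual fits.
#' @export
match_ttcs_per_map <- function(dataset, table, model, q_values = NULL,
                               k_neighbors = 4, bounds = list(),
                               pop_size = NULL, f_weight = 0.7, cr = 0.9,
                               max_iter = 1500, seed = 1L) {
  set <- assemble_experimental_set(dataset, q_values)
  fits <- lapply(seq_along(set$ttcs), function(j) {
    sub <- list(ttcs = set$ttcs[j], meta = set$meta[j, , drop = FALSE],
                times = dataset$times)
    match_ttcs(sub, table, model, monotone_eps = FALSE,
               k_neighbors = k_neighbors, bounds = bounds,
               pop_size = pop_size, f_weight = f_weight, cr = cr,
               max_iter = max_iter, seed = seed + j)
  })
  per_map <- dplyr::bind_rows(lapply(seq_along(fits), function(j) {
    f <- fits[[j]]
    tibble::tibble(condition = set$meta$condition[j],
                   q_um = set$meta$q_um[j],
                   eps = f$per_condition$eps,
                   psi_gel = f$per_condition$psi_gel,
                   t_start = f$calibration$t_start,
                   t_end = f$calibration$t_end,
                   c_q = f$calibration$c_q,
                   D = f$D)
  }))
  per_condition <- per_map |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(eps = mean(.data$eps), psi_gel = mean(.data$psi_gel),
                     .groups = "drop")
  structure(list(
    per_condition = per_condition,
    per_map = per_map,
    calibration = list(t_start = mean(per_map$t_start),
                       t_end = mean(per_map$t_end),
                       c_q = mean(per_map$c_q)),
    D = mean(per_map$D),
    objective_value = -mean(per_map$D),
    history = fits[[1]]$history,
    n_evals = sum(vapply(fits, `[[`, numeric(1), "n_evals")),
    settings = fits[[1]]$settings,
    q_values = sort(unique(per_map$q_um))
  ), class = "match_result")
}

# Running maximum with argmax, used by the monotone dynamic programme.
cummax_with_index <- function(x) {
  v <- numeric(length(x))
  ix <- integer(length(x))
  best <- -Inf
  bi <- 0L
  for (i in seq_along(x)) {
    if (x[i] > best) {
      best <- x[i]
      bi <- i
    }
    v[i] <- best
    ix[i] <- bi
  }
  list(value = v, index = ix)
}

# Best per-condition sample chain under the constraint that the chosen
# eps values are non-increasing across the condition rows (conditions
# ordered by increasing quench temperature). Exact dynamic programme over
# the samples sorted by decreasing eps; ties in eps are allowed
# predecessors. Returns the chosen sample index per condition.
monotone_best_chain <- function(score, eps) {
  n_c <- nrow(score)
  n_s <- ncol(score)
  ord <- order(-eps)
  eps_sorted <- eps[ord]
  hi <- vapply(seq_len(n_s), function(j) {
    max(which(eps_sorted >= eps_sorted[j] - 1e-12))
  }, integer(1))
  sc <- score[, ord, drop = FALSE]
  best <- matrix(-Inf, n_c, n_s)
  pick <- matrix(NA_integer_, n_c, n_s)
  best[1, ] <- sc[1, ]
  if (n_c > 1) {
    for (ci in 2:n_c) {
      run_prev <- cummax_with_index(best[ci - 1, ])
      best[ci, ] <- sc[ci, ] + run_prev$value[hi]
      pick[ci, ] <- run_prev$index[hi]
    }
  }
  end <- which.max(best[n_c, ])
  sel <- integer(n_c)
  sel[n_c] <- end
  if (n_c > 1) {
    for (ci in (n_c - 1):1) sel[ci] <- pick[ci + 1, sel[ci + 1]]
  }
  ord[sel]
}
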