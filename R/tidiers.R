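#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-condition parameters of a match result
#'
#' @param x A \code{match_result}.
#' @param ... Unused.
#' @return A tibble with one row per quench condition: \code{condition},
#'   \code{eps}, \code{psi_gel}, and the gel-point concentration
#'   \code{phi_gel}.
#' @export
tidy.match_result <- function(x, ...) {
  dplyr::mutate(x$per_condition, phi_gel = psi_to_phi(.data$psi_gel))
}

#' One-row summary of a match result
#'
#' @param x A \code{match_result}.
#' @param ... Unused.
#' @return A tibble with the best objective \code{D}, the calibration
#'   parameters, and optimisation bookkeeping.
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    t_start = x$calibration$t_start,
    t_end = x$calibration$t_end,
    c_q = x$calibration$c_q,
    n_conditions = nrow(x$per_condition),
    n_evals = x$n_evals,
    n_iter = length(x$history)
  )
}

#' @export
autoplot.match_result <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$history),
                       D = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$D)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DE generation", y = "best D",
                  title = "Differential-evolution convergence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ch_field <- function(object, ...) {
  n <- nrow(object$values)
  df <- tibble::tibble(
    x = rep(seq_len(n), times = n),
    y = rep(seq_len(n), each = n),
    psi = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$psi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("order parameter, t = %g", object$time)) +
    ggplot2::theme_void()
}

ttc_raster <- function(values, times, title) {
  n <- nrow(values)
  df <- tibble::tibble(
    t1 = rep(times, times = n),
    t2 = rep(times, each = n),
    C = as.vector(values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2, fill = .data$C)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "t1", y = "t2", title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ttc_map <- function(object, ...) {
  ttc_raster(object$values, object$times,
             sprintf("TTC at q = %g (%s)", object$q_center, object$source))
}

#' @export
autoplot.preprocessed_ttc <- function(object, ...) {
  ttc_raster(object$values, seq_len(object$s),
             sprintf("preprocessed TTC (%dx%d)", object$s, object$s))
}
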