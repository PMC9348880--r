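#' Binodal compositions of the Landau free energy
#'
#' For the quartic free-energy density
#' \eqn{f(\Psi) = -\frac{\epsilon}{2}\Psi^2 + \frac14\Psi^4}, the
#' coexisting (binodal) compositions are the minima
#' \eqn{\Psi = \pm\sqrt{\epsilon}}.
#'
#' @param eps Quench depth(s), non-negative.
#' @return A tibble with columns \code{eps}, \code{psi_low},
#'   \code{psi_high}.
#' @export
binodal <- function(eps) {
  if (any(eps < 0)) {
    stop(errorCondition("binodal undefined for eps < 0",
                        class = "specklematch_domain_error"))
  }
  tibble::tibble(eps = eps, psi_low = -sqrt(eps), psi_high = sqrt(eps))
}

#' Spinodal compositions of the Landau free energy
#'
#' The stability boundary where \eqn{f''(\Psi) = -\epsilon + 3\Psi^2 = 0},
#' i.e. \eqn{\Psi = \pm\sqrt{\epsilon/3}}. Always inside the binodal.
#'
#' @param eps Quench depth(s), non-negative.
#' @return A tibble with columns \code{eps}, \code{psi_low},
#'   \code{psi_high}.
#' @export
spinodal <- function(eps) {
  if (any(eps < 0)) {
    stop(errorCondition("spinodal undefined for eps < 0",
                        class = "specklematch_domain_error"))
  }
  tibble::tibble(eps = eps, psi_low = -sqrt(eps / 3), psi_high = sqrt(eps / 3))
}

#' Map the order parameter to a concentration fraction
#'
#' Affine symmetric lattice-gas convention: \eqn{\Phi = (1 + \Psi)/2},
#' mapping \eqn{\Psi \in [-1, 1]} monotonically onto \eqn{[0, 1]}.
#' Isolated here so an alternative calibration can be swapped in.
#'
#' @param psi Order-parameter value(s).
#' @return Concentration fraction(s).
#' @export
psi_to_phi <- function(psi) (1 + psi) / 2

#' Gel line from fitted parameters
#'
#' Places each fitted condition on the phase diagram at its
#' \code{(eps, psi_gel)} and maps the gelation point to a concentration.
#' With gelation points that rise for shallower quenches, the resulting
#' line bends towards the spinodal for deeper quenches, i.e. the dense
#' phase arrests at lower concentration the deeper the quench.
#'
#' @param results A \code{match_result}, or a data frame with columns
#'   \code{eps} and \code{psi_gel} (optionally \code{condition}).
#' @return A tibble of gel points: \code{condition}, \code{eps},
#'   \code{psi}, \code{phi}, \code{role = "gel"}, ordered by \code{eps}.
#' @export
gel_line <- function(results) {
  df <- if (inherits(results, "match_result")) {
    results$per_condition
  } else {
    tibble::as_tibble(results)
  }
  stopifnot(nrow(df) >= 1, all(c("eps", "psi_gel") %in% names(df)))
  if (!"condition" %in% names(df)) df$condition <- seq_len(nrow(df))
  out <- tibble::tibble(
    condition = df$condition,
    eps = df$eps,
    psi = df$psi_gel,
    phi = psi_to_phi(df$psi_gel),
    role = "gel"
  )
  dplyr::arrange(out, .data$eps)
}

#' Phase-boundary curves for plotting
#'
#' @param eps_max Largest quench depth on the curves.
#' @param n Number of points per branch.
#' @return Long tibble with columns \code{role} (binodal/spinodal),
#'   \code{branch}, \code{eps}, \code{psi}, \code{phi}.
#' @export
phase_boundaries <- function(eps_max = 1, n = 200) {
  eps <- seq(0, eps_max, length.out = n)
  bi <- binodal(eps)
  sp <- spinodal(eps)
  dplyr::bind_rows(
    tibble::tibble(role = "binodal", branch = "low", eps = eps, psi = bi$psi_low),
    tibble::tibble(role = "binodal", branch = "high", eps = eps, psi = bi$psi_high),
    tibble::tibble(role = "spinodal", branch = "low", eps = eps, psi = sp$psi_low),
    tibble::tibble(role = "spinodal", branch = "high", eps = eps, psi = sp$psi_high)
  ) |>
    dplyr::mutate(phi = psi_to_phi(.data$psi))
}

#' Plot the phase diagram with an optional gel line
#'
#' Concentration on the horizontal axis, quench depth increasing downwards
#' (deeper quench = lower temperature), with binodal and spinodal curves
#' and, if supplied, the fitted gel points.
#'
#' @param gel Optional gel-point tibble from \code{\link{gel_line}} (or a
#'   \code{match_result}).
#' @param eps_max Depth range of the boundary curves.
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(gel = NULL, eps_max = 1) {
  pb <- phase_boundaries(eps_max)
  p <- ggplot2::ggplot(pb, ggplot2::aes(x = .data$phi, y = .data$eps)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$role,
                                    group = interaction(.data$role, .data$branch))) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(Phi), y = expression(epsilon),
                  linetype = NULL,
                  title = "Landau phase diagram",
                  subtitle = "quench depth increases downwards") +
    ggplot2::theme_minimal()
  if (!is.null(gel)) {
    if (inherits(gel, "match_result")) gel <- gel_line(gel)
    p <- p + ggplot2::geom_point(data = gel, colour = "firebrick", size = 2) +
      ggplot2::geom_path(data = gel, colour = "firebrick", linewidth = 0.3)
  }
  p
}
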