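#' Plot the energy landscape
#'
#' Filled-contour view of \eqn{U(r, \alpha)} over the bound region, with
#' the transition angle and the rupture boundary marked.
#'
#' @inheritParams landscape_grid
#' @param max_energy Energies above this value (kBT above the minimum) are
#'   clipped for display.
#' @return A ggplot object.
#' @export
plot_landscape <- function(params, env = bond_environment(), force = 0,
                           max_energy = 40, n_r = 121, n_alpha = 181) {
  params <- as_bond_parameters(params)
  g <- landscape_grid(params, env, force, n_r = n_r, n_alpha = n_alpha)
  g$energy <- pmin(g$energy - min(g$energy), max_energy)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$alpha, y = .data$r)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$energy)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$energy),
                          colour = "white", alpha = 0.4, bins = 12) +
    ggplot2::geom_vline(xintercept = params$alpha_c, linetype = 2,
                        colour = "white") +
    ggplot2::geom_hline(yintercept = params$r0 + params$d, linetype = 3,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "U (kBT)") +
    ggplot2::labs(x = "inter-domain angle alpha (deg)", y = "r (nm)",
                  title = sprintf("bond energy landscape, F = %g pN", force))
}

#' Plot a kinetic solution
#'
#' Mean bond lifetime (and the large-angle state duration) versus force on
#' a log time axis — the standard catch-bond presentation.
#'
#' @param object A [kinetic_solution()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bond_kinetics
#' @export
autoplot.bond_kinetics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("tau", "tau_l"),
                              names_to = "quantity", values_to = "seconds")
  long$quantity <- dplyr::recode(long$quantity,
                                 tau = "mean bond lifetime",
                                 tau_l = "large-angle state duration")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$force, y = .data$seconds,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "force (pN)", y = "time (s)", colour = NULL)
}

#' Plot an empirical survival curve against the model
#'
#' @param object A [simulate_rupture_times()] ensemble (or any lifetime
#'   tibble with `lifetime`/`censored`).
#' @param solution Optional single-force [kinetic_solution()] whose
#'   analytic survival curve is overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rupture_ensemble
#' @export
autoplot.rupture_ensemble <- function(object, solution = NULL, ...) {
  km <- empirical_survival(object)
  p <- ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2) +
    ggplot2::labs(x = "time (s)", y = "survival probability")
  if (!is.null(solution)) {
    tt <- seq(0, max(km$time), length.out = 200)
    an <- survival_probability(solution, tt)
    p <- p + ggplot2::geom_line(data = an,
                                ggplot2::aes(x = .data$time,
                                             y = .data$survival),
                                colour = "firebrick")
  }
  p
}

#' Plot a landscape fit
#'
#' Per-force empirical mean lifetimes of the fitted dataset with the
#' fitted model's lifetime curve.
#'
#' @param object A `bond_fit`.
#' @param forces Force grid for the model curve; defaults to a dense grid
#'   over the data range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bond_fit
#' @export
autoplot.bond_fit <- function(object, forces = NULL, ...) {
  dat <- object$data
  emp <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(dat),
                                          .data$force),
                          mean_lifetime = mean(.data$lifetime),
                          se = stats::sd(.data$lifetime) / sqrt(dplyr::n()),
                          .groups = "drop")
  if (is.null(forces)) {
    forces <- seq(min(dat$force), max(dat$force), length.out = 60)
  }
  curve <- kinetic_solution(forces, object$best_params, object$env,
                            object$measure, object$rate_eval,
                            object$control)
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$force,
                                    y = .data$mean_lifetime)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_lifetime - .data$se,
      ymax = .data$mean_lifetime + .data$se)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$force, y = .data$tau),
                       colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "force (pN)", y = "mean bond lifetime (s)")
}
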