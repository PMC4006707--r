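## ggplot2 front-ends for the result containers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory: potentials and ion concentrations vs time
#'
#' Two stacked panels in the style of the classic figures: membrane and
#' reversal potentials on top, ion concentrations below.
#'
#' @param object An `ion_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ion_trajectory <- function(object, ...) {
  pots <- tidyr::pivot_longer(
    dplyr::select(object, "t_s", "V", dplyr::any_of(c("E_Na", "E_K", "E_Cl"))),
    -"t_s", names_to = "series", values_to = "mV")
  pots$panel <- "potentials (mV)"
  conc <- tidyr::pivot_longer(
    dplyr::select(object, "t_s",
                  dplyr::any_of(c("Na_i", "Na_e", "K_i", "K_e",
                                  "Cl_i", "Cl_e"))),
    -"t_s", names_to = "series", values_to = "mV")
  conc$panel <- "concentrations (mMol/l)"
  dat <- dplyr::bind_rows(pots, conc)
  ggplot2::ggplot(dat, ggplot2::aes(.data$t_s, .data$mV,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuation branch (bifurcation diagram)
#'
#' Membrane potential of the fixed point against the continuation
#' parameter; unstable sections dashed, detected bifurcations marked.
#'
#' @param object An `ion_branch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ion_branch <- function(object, ...) {
  p_name <- attr(object, "p_name")
  d <- tibble::as_tibble(as.data.frame(object))
  d$stability <- ifelse(d$max_re < 0, "stable", "unstable")
  b <- bifurcations(object)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data[[p_name]], .data$V)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$stability,
                                    group = 1), linewidth = 0.5) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = expression(rho ~ (mu * A / cm^2)),
                  y = "fixed-point V (mV)") +
    ggplot2::theme_minimal()
  if (nrow(b)) {
    gg <- gg + ggplot2::geom_point(data = b,
      ggplot2::aes(.data[[p_name]], .data$V), colour = "red", size = 2) +
      ggplot2::geom_text(data = b,
        ggplot2::aes(.data[[p_name]], .data$V, label = .data$type),
        vjust = -1, size = 3)
  }
  gg
}

#' Plot nullcline curves in the (K_i, Na_i) projection
#'
#' @param x Result of [nullcline_intersections()].
#' @param params Model parameters (for the unphysical-region boundaries).
#' @return A ggplot object.
#' @export
plot_nullclines <- function(x, params = ion_params()) {
  d <- dplyr::bind_rows(
    dplyr::mutate(x$curve_K, curve = "dK_i/dt = 0"),
    dplyr::mutate(x$curve_Na, curve = "dNa_i/dt = 0")
  )
  # Na_e >= 0 boundary: Na_i <= Na_i0 + (V_e/V_i) Na_e0; K_e >= 0: K_i <= ...
  na_cap <- params$Na_i0 + params$V_e / params$V_i * params$Na_e0
  k_cap <- params$K_i0 + params$V_e / params$V_i * params$K_e0
  ggplot2::ggplot(d, ggplot2::aes(.data$K_i, .data$Na_i,
                                  colour = .data$curve)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = na_cap, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = k_cap, linetype = "dotted") +
    ggplot2::labs(x = "K_i (mMol/l)", y = "Na_i (mMol/l)", colour = NULL) +
    ggplot2::theme_minimal()
}
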