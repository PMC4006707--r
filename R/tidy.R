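## broom-style tidiers for fitted/computed objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixed point
#'
#' One row per state variable plus the derived sodium concentration, with
#' the eigenvalue spectrum available via [glance.ion_fixed_point()].
#'
#' @param x An `ion_fixed_point`.
#' @param ... Unused.
#' @return A tibble with columns `variable`, `value`.
#' @export
tidy.ion_fixed_point <- function(x, ...) {
  s <- x$state
  der <- derive_state(s, x$params, x$config, rho = x$rho)
  tibble::tibble(
    variable = c(names(s), "Na_i", "Na_e", "K_e", "Cl_e",
                 "E_Na", "E_K", "E_Cl", "I_p"),
    value = c(unname(s), der$Na_i, der$Na_e, der$K_e, der$Cl_e,
              der$E_Na, der$E_K, der$E_Cl, der$I_p)
  )
}

#' @rdname tidy.ion_fixed_point
#' @export
glance.ion_fixed_point <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, V = x$state[["V"]], residual = x$residual,
    n_stable = x$n_stable, n_unstable = x$n_unstable,
    classification = x$classification, converged = x$converged,
    max_re = max(Re(x$eigenvalues)),
    leading_imag = abs(Im(x$eigenvalues[1]))
  )
}

#' Tidy a continuation branch
#'
#' @param x An `ion_branch`.
#' @param ... Unused.
#' @return The branch as a plain tibble (one row per continuation step).
#' @export
tidy.ion_branch <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.ion_branch
#' @export
glance.ion_branch <- function(x, ...) {
  b <- bifurcations(x)
  p_name <- attr(x, "p_name")
  tibble::tibble(
    n_points = nrow(x),
    p_min = min(x[[p_name]]), p_max = max(x[[p_name]]),
    n_LP = sum(b$type == "LP"), n_HB = sum(b$type == "HB"),
    status = attr(x, "status")
  )
}

#' Tidy an event report
#' @param x An `ion_events` object.
#' @param ... Unused.
#' @return One-row tibble with the event summary.
#' @export
tidy.ion_events <- function(x, ...) {
  tibble::tibble(
    n_spikes = x$n_spikes,
    fes_entry_s = x$fes_entry / 1e3,
    fes_exit_s = x$fes_exit / 1e3,
    fes_duration_s = x$fes_duration / 1e3,
    classification = x$classification,
    hyperpolarization_min = x$hyperpolarization_min
  )
}
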