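## Hodgkin-Huxley gating kinetics (shifted-voltage convention, resting
## potential near -68 mV) and the two reductions used throughout: adiabatic
## elimination of the fast sodium activation m, and replacement of the sodium
## inactivation h by a sigmoidal function of the potassium activation n.

# alpha/beta rate functions, 1/ms, V in mV.  The x/(1-exp(-x/10)) forms have
# a removable singularity; evaluate the analytic limit near it.
.alpha_n <- function(V) {
  x <- V + 34
  ifelse(abs(x) < 1e-6, 0.1 * (1 + x / 20), 0.01 * x / (1 - exp(-x / 10)))
}
.beta_n <- function(V) 0.125 * exp(-(V + 44) / 80)

.alpha_m <- function(V) {
  x <- V + 30
  ifelse(abs(x) < 1e-6, 1 * (1 + x / 20), 0.1 * x / (1 - exp(-x / 10)))
}
.beta_m <- function(V) 4 * exp(-(V + 55) / 18)

.alpha_h <- function(V) 0.07 * exp(-(V + 44) / 20)
.beta_h <- function(V) 1 / (1 + exp(-(V + 14) / 10))

#' Steady-state gating variables and the n-gate relaxation time
#'
#' Voltage-dependent asymptotic values of the three Hodgkin-Huxley gating
#' variables and the relaxation time of the potassium activation gate.  The
#' fast sodium activation `m` is eliminated adiabatically in the reduced
#' models, i.e. `m = m_inf(V)` is substituted wherever `m` occurs.
#'
#' @param V Membrane potential, mV.  Vectorised.
#' @param params Model parameters from [ion_params()]; only the gating
#'   timescale `phi_gate` (1/ms) is used.
#'
#' @return A tibble with columns `V`, `n_inf`, `m_inf`, `h_inf` (all
#'   dimensionless, in (0, 1)) and `tau_n` (ms).
#' @examples
#' gating_steady_states(seq(-100, 40, by = 20))
#' @export
gating_steady_states <- function(V, params = ion_params()) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  an <- .alpha_n(V); bn <- .beta_n(V)
  am <- .alpha_m(V); bm <- .beta_m(V)
  ah <- .alpha_h(V); bh <- .beta_h(V)
  tibble::tibble(
    V = V,
    n_inf = an / (an + bn),
    m_inf = am / (am + bm),
    h_inf = ah / (ah + bh),
    tau_n = 1 / (params$phi_gate * (an + bn))
  )
}

## Coefficients of the sigmoidal h(n) fit.  Obtained by simulating the
## membrane model (V, n, h; m adiabatic) at fixed Table-1 ion concentrations
## under constant current drives spanning rest to strong depolarisation and
## fitting h = 1/(1 + exp((n - theta)/sigma)) to the pooled (n, h) samples;
## see fit_h_of_n() and the methods vignette.  A linear fit h ~ 1 - n would
## go negative at the large n of the depolarised fixed point; the sigmoid
## keeps h in (0, 1) for all n.
.h_fit <- c(theta = 0.4837195, sigma = 0.1143457)

#' Sodium inactivation as a sigmoidal function of potassium activation
#'
#' The reduced models replace the sodium inactivation gate `h` by a fitted
#' sigmoid of the potassium activation `n`,
#' `h(n) = 1 / (1 + exp((n - theta) / sigma))`.  This plays the role of the
#' classical linear `h ~ 1 - n` relation but remains non-negative at the
#' large `n` values reached in the depolarised free-energy-starved state.
#'
#' @param n Potassium activation, dimensionless in \[0, 1\].  Vectorised.
#' @param coef Named numeric vector with elements `theta` and `sigma`;
#'   defaults to the packaged fit.
#' @return Sodium inactivation `h` in (0, 1).
#' @seealso [fit_h_of_n()] to re-derive the coefficients.
#' @examples
#' h_of_n(c(0.065, 0.5, 0.9))
#' @export
h_of_n <- function(n, coef = NULL) {
  if (is.null(coef)) coef <- .h_fit
  stopifnot(is.numeric(n), all(is.finite(n)))
  if (any(n < 0 | n > 1)) stop("n must lie in [0, 1]", call. = FALSE)
  1 / (1 + exp((n - coef[["theta"]]) / coef[["sigma"]]))
}

#' Re-derive the sigmoidal h(n) reduction from membrane dynamics
#'
#' Simulates the three-variable membrane model (V, n, h with adiabatic m) at
#' fixed equilibrium ion concentrations under a set of constant applied
#' currents, pools the visited (n, h) pairs, and fits the sigmoid
#' `h = 1/(1 + exp((n - theta)/sigma))` by nonlinear least squares.
#'
#' @param params Model parameters from [ion_params()].
#' @param currents Applied current amplitudes, uA/cm^2, spanning quiescence
#'   to strong drive.
#' @param t_end Simulated time per drive, ms.
#' @return List with elements `coef` (named vector theta, sigma), `linear`
#'   (coefficients of the comparison linear fit) and `data` (tibble of
#'   samples).
#' @export
fit_h_of_n <- function(params = ion_params(),
                       currents = c(0, 2, 5, 10, 20, 40, 80, 150),
                       t_end = 200) {
  p <- params
  E_Na <- nernst_potential(+1, p$Na_e0, p$Na_i0, p$phi_T)
  E_K <- nernst_potential(+1, p$K_e0, p$K_i0, p$phi_T)
  E_Cl <- nernst_potential(-1, p$Cl_e0, p$Cl_i0, p$phi_T)
  deriv <- function(t, y, Iapp) {
    V <- y[1]; n <- y[2]; h <- y[3]
    m <- .alpha_m(V) / (.alpha_m(V) + .beta_m(V))
    I_Na <- (p$g_Na_leak + p$g_Na_gated * m^3 * h) * (V - E_Na)
    I_K <- (p$g_K_leak + p$g_K_gated * n^4) * (V - E_K)
    I_Cl <- p$g_Cl_leak * (V - E_Cl)
    list(c(
      (-(I_Na + I_K + I_Cl) + Iapp) / p$C_m,
      p$phi_gate * (.alpha_n(V) * (1 - n) - .beta_n(V) * n),
      p$phi_gate * (.alpha_h(V) * (1 - h) - .beta_h(V) * h)
    ))
  }
  g0 <- gating_steady_states(p$V0, p)
  y0 <- c(V = p$V0, n = g0$n_inf, h = g0$h_inf)
  dat <- purrr::map_dfr(currents, function(I) {
    out <- deSolve::ode(y0, seq(0, t_end, by = 0.02), deriv, I,
      method = "lsoda", rtol = 1e-8, atol = 1e-8
    )
    d <- tibble::as_tibble(as.data.frame(out))
    names(d) <- c("time", "V", "n", "h")
    d[d$time > 5, c("n", "h")]
  })
  fit <- stats::nls(h ~ 1 / (1 + exp((n - theta) / sigma)),
    data = dat, start = list(theta = 0.4, sigma = 0.1)
  )
  lin <- stats::coef(stats::lm(h ~ n, data = dat))
  list(coef = stats::coef(fit), linear = lin, data = dat)
}
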