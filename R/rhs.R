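## Right-hand side of every model variant, plus the unreduced (degenerate)
## system kept for the conservation-law diagnostics.

#' Time derivative of the reduced model state
#'
#' Rate equations of the configured model variant.  The independent
#' variables are `V`, `n` (gated configurations), `K_i`, `Cl_i` (chloride
#' on) and `K_e` (potassium-bath coupling); intracellular sodium follows
#' from the charge-conservation constraint and the extracellular
#' concentrations from mass conservation.  An applied `NA_PULSE` current is
#' a sodium current: it enters the voltage rate directly and reaches the
#' sodium bookkeeping through the charge constraint, which is exactly the
#' consistency rule that makes the reduction well-posed.
#'
#' @param t Time, ms (only used by protocols).
#' @param state Named state vector, see [reference_state()].
#' @param params,config Model parameters and configuration.
#' @param protocol Stimulation protocol from [ion_protocol()].
#' @param rho Override of the maximal pump current (continuation parameter).
#' @return Named vector of time derivatives of the independent variables
#'   (mV/ms, 1/ms, mMol/l/ms).
#' @export
ion_rhs <- function(t, state, params, config = ion_config(),
                    protocol = ion_protocol("NONE"), rho = NULL) {
  p <- params
  if (is.null(rho)) rho <- if (config$pump_model == "A") p$rho_pump else p$Imax_B
  I_app <- 0
  if (protocol$kind == "NA_PULSE" && t >= protocol$t_on && t < protocol$t_off) {
    I_app <- protocol$amplitude
  }
  if (protocol$kind == "PUMP_OFF" && t >= protocol$t_on && t < protocol$t_off) {
    rho <- 0
  }
  d <- derive_state(state, p, config, rho = rho)
  gflux <- .gamma_flux(p)
  out <- c(V = (-(d$I_Na + d$I_K + d$I_Cl + d$I_p) + I_app) / p$C_m)
  if (config$gating == "GATED") {
    V <- d$V
    out["n"] <- p$phi_gate * (.alpha_n(V) * (1 - d$n) - .beta_n(V) * d$n)
  }
  out["K_i"] <- -gflux / p$V_i * (d$I_K - 2 * d$I_p)
  if (config$chloride) out["Cl_i"] <- gflux / p$V_i * d$I_Cl
  if (config$bath == "K_BATH") {
    out["K_e"] <- gflux / p$V_e * (d$I_K - 2 * d$I_p) +
      bath_term(d$K_e, p)
  }
  out[state_names(config)]
}

# unreduced system (V, n, Na_i, K_i, Cl_i): sodium kept as an independent
# variable.  Its Jacobian is singular everywhere (exact linear dependence of
# V and the intracellular charge concentration); retained only to verify
# that degeneracy and the conserved quantity.
ion_rhs_full <- function(t, state, params, config = ion_config(), rho = NULL) {
  p <- params
  if (is.null(rho)) rho <- if (config$pump_model == "A") p$rho_pump else p$Imax_B
  V <- state[["V"]]; n <- state[["n"]]
  Na_i <- state[["Na_i"]]; K_i <- state[["K_i"]]; Cl_i <- state[["Cl_i"]]
  r <- p$V_i / p$V_e
  Na_e <- p$Na_e0 + r * (p$Na_i0 - Na_i)
  K_e <- p$K_e0 + r * (p$K_i0 - K_i)
  Cl_e <- p$Cl_e0 + r * (p$Cl_i0 - Cl_i)
  E_Na <- nernst_potential(+1, Na_e, Na_i, p$phi_T)
  E_K <- nernst_potential(+1, K_e, K_i, p$phi_T)
  E_Cl <- nernst_potential(-1, Cl_e, Cl_i, p$phi_T)
  m <- .alpha_m(V) / (.alpha_m(V) + .beta_m(V))
  h <- h_of_n(min(max(n, 0), 1))
  I_Na <- (p$g_Na_leak + p$g_Na_gated * m^3 * h) * (V - E_Na)
  I_K <- (p$g_K_leak + p$g_K_gated * n^4) * (V - E_K)
  I_Cl <- p$g_Cl_leak * (V - E_Cl)
  I_p <- .pump_current_raw(Na_i, K_e, rho, config$pump_model)
  gflux <- .gamma_flux(p)
  c(V = -(I_Na + I_K + I_Cl + I_p) / p$C_m,
    n = p$phi_gate * (.alpha_n(V) * (1 - n) - .beta_n(V) * n),
    Na_i = -gflux / p$V_i * (I_Na + 3 * I_p),
    K_i = -gflux / p$V_i * (I_K - 2 * I_p),
    Cl_i = gflux / p$V_i * I_Cl)
}

#' Conserved charge-potential combination of the closed model
#'
#' In closed configurations the quantity
#' `V - (V_i / (gamma C_m)) (Na_i + K_i - Cl_i)` is exactly conserved along
#' trajectories (the same linear dependence that makes the unreduced
#' Jacobian singular).  Useful as an integration-quality diagnostic.
#'
#' @inheritParams ion_rhs
#' @return Numeric scalar (mV-scale).
#' @export
conserved_charge <- function(state, params, config = ion_config()) {
  p <- params
  Na_i <- if ("Na_i" %in% names(state)) state[["Na_i"]] else
    na_from_charge_constraint(state, p, config)
  Cl_i <- if ("Cl_i" %in% names(state)) state[["Cl_i"]] else p$Cl_i0
  state[["V"]] - p$V_i / (.gamma_flux(p) * p$C_m) *
    (Na_i + state[["K_i"]] - Cl_i)
}
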