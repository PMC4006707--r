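## Membrane currents (Nernst and GHK), pump models, bath coupling, and the
## algebraic constraints (mass conservation, charge conservation) that close
## the reduced state.

# constant-field (GHK) current density, uA/cm^2.
# I = P * ALPHA * z * w * (c_i - c_e exp(-w)) / (1 - exp(-w)), w = z V/phi_T,
# with ALPHA = 9.6485 converting (um/s * mMol/l) to uA/cm^2.  Evaluated
# stably across w -> 0 and |w| large.
.ghk_alpha <- 9.6485

.ghk_current <- function(P, z, V, c_i, c_e, phi_T) {
  w <- z * V / phi_T
  wf <- ifelse(abs(w) < 1e-6,
    (c_i - c_e) + w * (c_i + c_e) / 2,            # series limit of w*f
    ifelse(w > 35, w * c_i,
      ifelse(w < -35, w * c_e,
        w * (c_i - c_e * exp(-w)) / (1 - exp(-w)))))
  P * .ghk_alpha * z * wf
}

# independent state variables for a configuration, in canonical order
state_names <- function(config) {
  nm <- "V"
  if (config$gating == "GATED") nm <- c(nm, "n")
  nm <- c(nm, "K_i")
  if (config$chloride) nm <- c(nm, "Cl_i")
  if (config$bath == "K_BATH") nm <- c(nm, "K_e")
  nm
}

# reference (equilibrium) state vector for a configuration
reference_state <- function(params, config) {
  g0 <- gating_steady_states(params$V0, params)
  full <- c(V = params$V0, n = g0$n_inf, K_i = params$K_i0,
            Cl_i = params$Cl_i0, K_e = params$K_e0)
  full[state_names(config)]
}

#' Intracellular sodium from the charge-conservation constraint
#'
#' The unreduced model conserves the difference between the membrane
#' potential and the scaled intracellular charge concentration, which makes
#' its Jacobian singular.  The reduced model therefore eliminates the sodium
#' rate equation: `Na_i = Na_i0 - dK_i + dCl_i + (gamma C_m / V_i)(V - V0)`.
#' The voltage term carries the (tiny) membrane charge; without chloride the
#' `dCl_i` term is absent.
#'
#' @param state Named state vector (see [reference_state()]) or a list with
#'   elements `V`, `K_i` and (if configured) `Cl_i`.
#' @param params,config Model parameters and configuration.
#' @return Intracellular sodium, mMol/l.
#' @export
na_from_charge_constraint <- function(state, params, config = ion_config()) {
  p <- params
  dK <- p$K_i0 - state[["K_i"]]
  dCl <- if (config$chloride) state[["Cl_i"]] - p$Cl_i0 else 0
  Na_i <- p$Na_i0 + dK + dCl +
    .gamma_flux(p) * p$C_m / p$V_i * (state[["V"]] - p$V0)
  if (any(Na_i < 0)) {
    stop("charge constraint yields negative Na_i", call. = FALSE)
  }
  Na_i
}

#' Extracellular concentrations from mass conservation
#'
#' In a closed system the total amount of each species is conserved, so
#' `c_e = c_e0 + (V_i / V_e) (c_i0 - c_i)` for every species.  When the
#' model is coupled to a potassium bath, `K_e` is an independent dynamical
#' variable and is taken from the state instead.
#'
#' @inheritParams na_from_charge_constraint
#' @return Named vector with `Na_e`, `K_e` and (if configured) `Cl_e`,
#'   mMol/l.  A negative result is a hard error naming the species.
#' @export
ecs_from_ics <- function(state, params, config = ion_config()) {
  p <- params
  r <- p$V_i / p$V_e
  Na_i <- na_from_charge_constraint(state, p, config)
  out <- c(Na_e = p$Na_e0 + r * (p$Na_i0 - Na_i))
  out["K_e"] <- if (config$bath == "K_BATH") state[["K_e"]] else
    p$K_e0 + r * (p$K_i0 - state[["K_i"]])
  if (config$chloride) {
    out["Cl_e"] <- p$Cl_e0 + r * (p$Cl_i0 - state[["Cl_i"]])
  }
  neg <- names(out)[out < 0]
  if (length(neg)) {
    stop("negative extracellular concentration: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  out
}

# all derived quantities at a state: concentrations, reversal potentials,
# gating, currents, pump.  The workhorse behind rhs() and the trajectory
# derived series.
derive_state <- function(state, params, config, rho = NULL) {
  p <- params
  if (is.null(rho)) rho <- if (config$pump_model == "A") p$rho_pump else p$Imax_B
  V <- state[["V"]]
  K_i <- state[["K_i"]]
  Cl_i <- if (config$chloride) state[["Cl_i"]] else NA_real_
  Na_i <- na_from_charge_constraint(state, p, config)
  ecs <- ecs_from_ics(state, p, config)
  if (min(Na_i, K_i, ecs, if (config$chloride) Cl_i else Inf) < 0 ||
      (config$chloride && Cl_i < 0) || K_i < 0) {
    stop("negative ion concentration", call. = FALSE)
  }
  E_Na <- nernst_potential(+1, ecs[["Na_e"]], Na_i, p$phi_T)
  E_K <- nernst_potential(+1, ecs[["K_e"]], K_i, p$phi_T)
  E_Cl <- if (config$chloride) {
    nernst_potential(-1, ecs[["Cl_e"]], Cl_i, p$phi_T)
  } else NA_real_

  if (config$gating == "GATED") {
    n <- state[["n"]]
    m <- .alpha_m(V) / (.alpha_m(V) + .beta_m(V))
    h <- h_of_n(min(max(n, 0), 1))
    fNa <- m^3 * h
    fK <- n^4
  } else {
    n <- NA_real_; m <- NA_real_; h <- NA_real_
    fNa <- 0; fK <- 0
  }

  if (config$current_model == "NERNST") {
    I_Na <- (p$g_Na_leak + p$g_Na_gated * fNa) * (V - E_Na)
    I_K <- (p$g_K_leak + p$g_K_gated * fK) * (V - E_K)
    I_Cl <- if (config$chloride) p$g_Cl_leak * (V - E_Cl) else 0
  } else {
    I_Na <- .ghk_current(p$P_Na_leak + p$P_Na_gated * fNa, +1, V,
                         Na_i, ecs[["Na_e"]], p$phi_T)
    I_K <- .ghk_current(p$P_K_leak + p$P_K_gated * fK, +1, V,
                        K_i, ecs[["K_e"]], p$phi_T)
    I_Cl <- if (config$chloride) {
      .ghk_current(p$P_Cl_leak, -1, V, Cl_i, ecs[["Cl_e"]], p$phi_T)
    } else 0
  }
  I_p <- .pump_current_raw(Na_i, ecs[["K_e"]], rho, config$pump_model)
  list(V = V, n = n, m = m, h = h,
       Na_i = Na_i, K_i = K_i, Cl_i = Cl_i,
       Na_e = ecs[["Na_e"]], K_e = ecs[["K_e"]],
       Cl_e = if (config$chloride) ecs[["Cl_e"]] else NA_real_,
       E_Na = E_Na, E_K = E_K, E_Cl = E_Cl,
       I_Na = I_Na, I_K = I_K, I_Cl = I_Cl, I_p = I_p)
}

#' Membrane ion currents at a state
#'
#' Sodium, potassium and chloride current densities in the configured
#' formulation (Nernst or GHK), with the gated conductance factors `m^3 h`
#' and `n^4`.  Outward (cation efflux) currents are positive and
#' hyperpolarise the membrane.  With `chloride = FALSE` the chloride current
#' is identically zero.
#'
#' @inheritParams na_from_charge_constraint
#' @return Named vector `c(I_Na, I_K, I_Cl)`, uA/cm^2.
#' @export
membrane_currents <- function(state, params, config = ion_config()) {
  d <- derive_state(state, params, config)
  c(I_Na = d$I_Na, I_K = d$I_K, I_Cl = d$I_Cl)
}

# pump current for given Na_i, K_e; sigmoid arguments clamped to +-50
# before exponentiation so that extreme free-energy-starved states can
# never produce NaN/Inf.
.pump_current_raw <- function(Na_i, K_e, rho, pump_model) {
  if (pump_model == "A") {
    a1 <- pmin(pmax((25 - Na_i) / 3, -50), 50)
    a2 <- pmin(pmax(5.5 - K_e, -50), 50)
    rho / ((1 + exp(a1)) * (1 + exp(a2)))
  } else {
    Na_i <- pmax(Na_i, 1e-12); K_e <- pmax(K_e, 1e-12)
    rho * (Na_i / (Na_i + 10))^3 * (K_e / (K_e + 3.5))^2
  }
}

#' Na+/K+-ATPase pump current
#'
#' The ATP-driven exchange of intracellular sodium against extracellular
#' potassium at a 3:2 ratio.  Pump model A is a product of sigmoids in
#' `Na_i` and `K_e` saturating at `rho_pump`; pump model B is a saturating
#' Hill form (cubic in sodium occupancy, quadratic in potassium) saturating
#' at `Imax_B`.  The net charge current entering the voltage equation is
#' `I_p`; the ion-flux contributions are `+3 I_p` on sodium and `-2 I_p` on
#' potassium.
#'
#' @inheritParams na_from_charge_constraint
#' @param rho Override of the maximal pump current (used by continuation);
#'   defaults to `rho_pump` (pump A) or `Imax_B` (pump B).
#' @return Pump current density, uA/cm^2.
#' @export
pump_current <- function(state, params, config = ion_config(), rho = NULL) {
  d <- derive_state(state, params, config, rho = rho)
  d$I_p
}

#' Potassium bath coupling term
#'
#' Diffusive coupling of extracellular potassium to an infinite bath (or a
#' phenomenological glial buffering term):
#' `rate = lambda_bath * (K_reg - K_e)`, mMol/l/ms.
#'
#' @param K_e Extracellular potassium, mMol/l.
#' @param params Model parameters (uses `lambda_bath`, `K_reg`).
#' @return Restoring rate, mMol/l/ms.
#' @export
bath_term <- function(K_e, params = ion_params()) {
  stopifnot(all(K_e >= 0))
  params$lambda_bath * (params$K_reg - K_e)
}

# calibrate pump model B so the default model's physiological fixed point
# is retained exactly: Imax_B such that the B-form equals the A-form pump
# current at the pump-A fixed point.
calibrate_pump_B <- function(params = NULL) {
  if (is.null(params)) params <- ion_params()
  cfg <- ion_config()
  fp <- find_fixed_point(params, cfg)
  d <- derive_state(fp$state, params, cfg)
  hill <- (d$Na_i / (d$Na_i + 10))^3 * (d$K_e / (d$K_e + 3.5))^2
  d$I_p / hill
}
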