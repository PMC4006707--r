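## Fixed points: damped Newton iteration on the reduced right-hand side,
## finite-difference Jacobians, eigenvalue classification, and the Donnan
## (pump-off) equilibrium.

# per-variable scales used for residual norms and arclength metrics
.var_scales <- function(nm) {
  sc <- c(V = 100, n = 1, K_i = 100, Cl_i = 100, K_e = 100)
  sc[nm]
}

# residual scales: V and n relax on ~ms, ion concentrations on ~1e4 ms; a
# common scaled norm weights them comparably.
.res_scales <- function(nm) {
  sc <- c(V = 1, n = 1, K_i = 1e-4, Cl_i = 1e-4, K_e = 1e-4)
  sc[nm]
}

# finite-difference Jacobian of the reduced rhs at a state
rhs_jacobian <- function(state, params, config, rho = NULL, rel_step = 1e-6) {
  nm <- state_names(config)
  f0 <- ion_rhs(0, state, params, config, rho = rho)
  J <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (j in seq_along(nm)) {
    d <- max(rel_step * abs(state[[nm[j]]]), 1e-9)
    yp <- state; ym <- state
    yp[nm[j]] <- state[[nm[j]]] + d
    ym[nm[j]] <- state[[nm[j]]] - d
    J[, j] <- (ion_rhs(0, yp, params, config, rho = rho) -
               ion_rhs(0, ym, params, config, rho = rho)) / (2 * d)
  }
  J
}

#' Locate a fixed point by damped Newton iteration
#'
#' Newton iteration on the reduced right-hand side with a central
#' finite-difference Jacobian.  Steps that increase the scaled residual or
#' leave the physical domain (negative concentrations) are halved up to 25
#' times.  The returned object carries the eigen-decomposition of the
#' Jacobian at the solution.
#'
#' @param params,config Model parameters and configuration.
#' @param guess Initial named state; defaults to the reference equilibrium.
#' @param rho Pump-rate override (continuation parameter).
#' @param tol Scaled residual tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `ion_fixed_point`: `state`, `rho`, `residual`,
#'   `eigenvalues` (sorted by decreasing real part), `n_stable`,
#'   `n_unstable`, `classification`, `converged`, `jacobian`.
#' @examples
#' \donttest{
#' fp <- find_fixed_point()
#' fp$state[["V"]]
#' }
#' @export
find_fixed_point <- function(params = ion_params(), config = ion_config(),
                             guess = NULL, rho = NULL, tol = 1e-10,
                             max_iter = 60) {
  nm <- state_names(config)
  if (is.null(guess)) guess <- reference_state(params, config)
  y <- guess[nm]
  rs <- .res_scales(nm)
  fn <- function(y) ion_rhs(0, y, params, config, rho = rho)
  f <- fn(y)
  for (it in seq_len(max_iter)) {
    nrm <- sqrt(sum((f / rs)^2))
    if (nrm < tol) break
    J <- tryCatch(rhs_jacobian(y, params, config, rho = rho),
                  error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- y + lam * step
      f_new <- tryCatch(fn(cand), error = function(e) NULL)
      if (!is.null(f_new) &&
          sum((f_new / rs)^2) <= sum((f / rs)^2) * (1 + 1e-9)) break
      lam <- lam / 2
      if (lam < 1e-7) { f_new <- NULL; break }
    }
    if (is.null(f_new)) break
    y <- y + lam * step
    f <- f_new
  }
  J <- tryCatch(rhs_jacobian(y, params, config, rho = rho),
                error = function(e)
                  rhs_jacobian(y, params, config, rho = rho,
                               rel_step = 1e-9))
  res <- sqrt(sum((fn(y) / rs)^2))
  new_fixed_point(y, params, config, rho, J, res, converged = res < 1e-8)
}

new_fixed_point <- function(state, params, config, rho, J, residual,
                            converged) {
  eig <- eigen(J)
  ord <- order(-Re(eig$values))
  ev <- eig$values[ord]
  ns <- sum(Re(ev) < 0)
  nu <- length(ev) - ns
  lead_complex <- abs(Im(ev[1])) > 1e-12
  cls <- if (nu == 0) {
    if (lead_complex) "STABLE_FOCUS" else "STABLE_NODE"
  } else if (ns > 0) "SADDLE" else "UNSTABLE"
  structure(list(
    state = state, rho = rho %||%
      (if (config$pump_model == "A") params$rho_pump else params$Imax_B),
    residual = residual, eigenvalues = ev, n_stable = ns, n_unstable = nu,
    classification = cls, converged = converged, jacobian = J,
    params = params, config = config
  ), class = "ion_fixed_point")
}

#' @export
print.ion_fixed_point <- function(x, ...) {
  cat(sprintf("<ion_fixed_point> V = %.3f mV  [%d,%d] %s  (rho = %.4g, residual %.2g)\n",
              x$state[["V"]], x$n_stable, x$n_unstable, x$classification,
              x$rho, x$residual))
  invisible(x)
}

#' Eigen-spectrum and stability signature of a fixed point
#'
#' @param fp An `ion_fixed_point`.
#' @param zero_tol Half-width of the neutral band: eigenvalues with
#'   `|Re| < zero_tol` are flagged as borderline.
#' @return List with `eigenvalues` (sorted by decreasing real part),
#'   `signature` `c(n_stable, n_unstable)`, `borderline` count and
#'   `leading_imag` (imaginary part of the leading eigenvalue pair).
#' @export
stability_spectrum <- function(fp, zero_tol = 1e-9) {
  stopifnot(inherits(fp, "ion_fixed_point"))
  ev <- fp$eigenvalues
  list(eigenvalues = ev,
       signature = c(n_stable = fp$n_stable, n_unstable = fp$n_unstable),
       borderline = sum(abs(Re(ev)) < zero_tol),
       leading_imag = abs(Im(ev[1])))
}

#' Donnan equilibrium (pump-off limit) of the closed model
#'
#' With no pump and no applied current, a stationary state requires every
#' membrane current to vanish, hence all Nernst potentials equal to the
#' membrane potential; together with (near-)electroneutrality of the
#' concentration changes this defines the Donnan equilibrium.  Solved by
#' root-finding on the reduced algebraic system (it is the unique fixed
#' point of the model at zero pump rate) starting from a depolarised
#' interior guess.
#'
#' @param params,config Model parameters and configuration.
#' @return An `ion_fixed_point` at `rho = 0`.
#' @export
donnan_state <- function(params = ion_params(), config = ion_config()) {
  nm <- state_names(config)
  p <- params
  ## electroneutral Donnan construction as the Newton seed: a common ratio
  ## r = c_i/c_e for cations (1/r for anions) with per-species mass
  ## conservation and conservation of the intracellular charge
  ## concentration; the exact state (including the tiny membrane-charge
  ## voltage term) is then refined on the full system.
  M_Na <- p$V_i * p$Na_i0 + p$V_e * p$Na_e0
  M_K <- p$V_i * p$K_i0 + p$V_e * p$K_e0
  M_Cl <- p$V_i * p$Cl_i0 + p$V_e * p$Cl_e0
  C0 <- p$Na_i0 + p$K_i0 - (if (config$chloride) p$Cl_i0 else 0)
  f <- function(r) {
    r * (M_Na + M_K) / (p$V_i * r + p$V_e) -
      (if (config$chloride) M_Cl / (p$V_i + r * p$V_e) else 0) - C0
  }
  r <- stats::uniroot(f, c(0.2, 5), tol = 1e-12)$root
  V_g <- p$phi_T * log(1 / r)
  g <- c(V = V_g,
         n = gating_steady_states(V_g, p)$n_inf,
         K_i = r * M_K / (p$V_i * r + p$V_e),
         Cl_i = M_Cl / (p$V_i + r * p$V_e),
         K_e = M_K / (p$V_i * r + p$V_e))
  fp <- find_fixed_point(params, config, guess = g[nm], rho = 0)
  if (!fp$converged) {
    stop("Donnan root solve did not converge: residual ",
         format(fp$residual, digits = 3), call. = FALSE)
  }
  fp
}
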