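## Scenario harnesses: the eight-variant sweep, geometry sweeps, the
## ionic-excitability demonstration with nullcline projections, and
## deterministic fixture generation.

variant_grid <- function() {
  tidyr::expand_grid(
    current_model = c("NERNST", "GHK"),
    pump_model = c("A", "B"),
    chloride = c(TRUE, FALSE)
  ) |>
    dplyr::mutate(variant = dplyr::row_number(), .before = 1)
}

#' Sweep the eight gated model variants (and their leak-only counterparts)
#'
#' For every combination of current model (Nernst/GHK), pump model (A/B)
#' and chloride (on/off), computes the bistable range of pump rates for the
#' gated configuration and classifies the leak-only counterpart (which has
#' a single monotone branch and no bistability).  Variants are numbered
#' 1-8 in lexicographic order of (current model, pump, chloride); the
#' numbering is declared in the output.
#'
#' @param params Model parameters.
#' @param rho_max Upper bound of the recovery-rate search, uA/cm^2.
#' @param leak_only Also classify the eight leak-only counterparts
#'   (doubles the run time).
#' @return Tibble with one row per variant: the configuration triple,
#'   `rho_min_phys`, `rho_recovery`, ratios to the default maximal pump
#'   rate, `bistable`, and (if requested) `leak_monostable`.
#' @export
variant_sweep <- function(params = ion_params(), rho_max = 400,
                          leak_only = TRUE) {
  grid <- variant_grid()
  rho0 <- params$rho_pump
  res <- purrr::pmap(grid, function(variant, current_model, pump_model,
                                    chloride) {
    cfg <- ion_config(current_model = current_model, pump_model = pump_model,
                      chloride = chloride, gating = "GATED")
    br <- tryCatch(bistable_range(params, cfg, rho_max = rho_max),
                   error = function(e) list(rho_min_phys = NA_real_,
                                            rho_recovery = NA_real_,
                                            monostable = NA))
    leak <- NA
    if (leak_only) {
      cfg_l <- ion_config(current_model = current_model,
                          pump_model = pump_model, chloride = chloride,
                          gating = "LEAK_ONLY")
      leak <- tryCatch({
        brl <- bistable_range(params, cfg_l, rho_max = rho_max)
        isTRUE(brl$monostable)
      }, error = function(e) NA)
    }
    tibble::tibble(
      variant = variant, current_model = current_model,
      pump_model = pump_model, chloride = chloride,
      rho_min_phys = br$rho_min_phys, rho_recovery = br$rho_recovery,
      ratio_min = br$rho_min_phys / rho0,
      ratio_recovery = br$rho_recovery / rho0,
      bistable = !isTRUE(br$monostable),
      leak_monostable = leak
    )
  })
  dplyr::bind_rows(res)
}

#' Geometry sweep: bifurcation loci over zeta and omega
#'
#' Wraps [two_parameter_curve()] for the membrane-surface scale
#' `zeta` in \[0.1, 10\] and the extracellular volume fraction `omega` in
#' \[0.02, 0.5\], for both edges of the bistable range, and returns one
#' tidy table.
#'
#' @param params,config Model parameters and configuration (default model).
#' @param zeta_values,omega_values Grids of the second parameter.
#' @return Tibble with columns `bif` ("LP"/"HB"), `second_param`, `value`,
#'   `rho`.
#' @export
geometry_sweep <- function(params = ion_params(), config = ion_config(),
                           zeta_values = NULL, omega_values = NULL) {
  pieces <- list()
  for (b in c("LP", "HB")) {
    z <- two_parameter_curve(params, config, bif = b,
                             second_param = "zeta", values = zeta_values)
    o <- two_parameter_curve(params, config, bif = b,
                             second_param = "omega", values = omega_values)
    pieces[[length(pieces) + 1]] <- dplyr::mutate(z, bif = b, .before = 1)
    pieces[[length(pieces) + 1]] <- dplyr::mutate(o, bif = b, .before = 1)
  }
  dplyr::bind_rows(pieces)
}

#' Nullcline curves of the slow ion subsystem in the (K_i, Na_i) plane
#'
#' For a chosen zeroed rate (`dK_i/dt = 0` or `dNa_i/dt = 0`), solves the
#' remaining fixed-point conditions (voltage and gating stationarity, and
#' potassium-bath stationarity in buffered configurations) along a grid of
#' `K_i` values, yielding a curve `Na_i(K_i)`.  Intersections of the two
#' curves are full fixed points of the model.  The unphysical-region
#' boundaries are the zero-level sets of the derived extracellular
#' concentrations (`Na_e >= 0`, `K_e >= 0`).
#'
#' @param params,config Model parameters and configuration.
#' @param which_rate `"K"` or `"Na"`.
#' @param K_i_grid Grid of intracellular potassium values, mMol/l.
#' @return Tibble with columns `K_i`, `Na_i`, `V`, `converged`.
#' @export
nullcline_curve <- function(params = ion_params(), config = ion_config(),
                            which_rate = c("K", "Na"),
                            K_i_grid = seq(60, 133, by = 0.5)) {
  which_rate <- match.arg(which_rate)
  p <- params
  buffered <- config$bath == "K_BATH"
  gflux <- .gamma_flux(p)
  ## unknowns: V, n, Na_i (+ K_e if buffered); K_i fixed per grid point.
  ## residuals: dV=0, dn=0, zeroed ion rate = 0 (+ dK_e = 0 if buffered).
  resid <- function(x, K_i) {
    V <- x[1]; n <- x[2]; Na_i <- x[3]
    K_e <- if (buffered) x[4] else p$K_e0 + p$V_i / p$V_e * (p$K_i0 - K_i)
    ## chloride from the charge constraint inverted for Na_i free
    Cl_i <- p$Cl_i0 + (Na_i - p$Na_i0) + (K_i - p$K_i0) -
      gflux * p$C_m / p$V_i * (V - p$V0)
    if (!config$chloride) Cl_i <- p$Cl_i0
    Na_e <- p$Na_e0 + p$V_i / p$V_e * (p$Na_i0 - Na_i)
    Cl_e <- p$Cl_e0 + p$V_i / p$V_e * (p$Cl_i0 - Cl_i)
    if (min(Na_e, K_e, Cl_e, Na_i, Cl_i) <= 0) return(NULL)
    E_Na <- nernst_potential(+1, Na_e, Na_i, p$phi_T)
    E_K <- nernst_potential(+1, K_e, K_i, p$phi_T)
    E_Cl <- if (config$chloride) nernst_potential(-1, Cl_e, Cl_i, p$phi_T)
            else NA_real_
    m <- .alpha_m(V) / (.alpha_m(V) + .beta_m(V))
    h <- h_of_n(min(max(n, 0), 1))
    if (config$current_model == "NERNST") {
      I_Na <- (p$g_Na_leak + p$g_Na_gated * m^3 * h) * (V - E_Na)
      I_K <- (p$g_K_leak + p$g_K_gated * n^4) * (V - E_K)
      I_Cl <- if (config$chloride) p$g_Cl_leak * (V - E_Cl) else 0
    } else {
      I_Na <- .ghk_current(p$P_Na_leak + p$P_Na_gated * m^3 * h, +1, V,
                           Na_i, Na_e, p$phi_T)
      I_K <- .ghk_current(p$P_K_leak + p$P_K_gated * n^4, +1, V,
                          K_i, K_e, p$phi_T)
      I_Cl <- if (config$chloride)
        .ghk_current(p$P_Cl_leak, -1, V, Cl_i, Cl_e, p$phi_T) else 0
    }
    rho <- if (config$pump_model == "A") p$rho_pump else p$Imax_B
    I_p <- .pump_current_raw(Na_i, K_e, rho, config$pump_model)
    out <- c(
      -(I_Na + I_K + I_Cl + I_p) / p$C_m,
      p$phi_gate * (.alpha_n(V) * (1 - n) - .beta_n(V) * n),
      if (which_rate == "K") -(I_K - 2 * I_p) else -(I_Na + 3 * I_p)
    )
    if (buffered) {
      out <- c(out,
               (gflux / p$V_e * (I_K - 2 * I_p) + bath_term(K_e, p)) * 1e4)
    }
    out
  }
  solve_pt <- function(K_i, x0) {
    x <- x0
    sc <- c(1, 1, 1e-1, if (buffered) 1e-1)
    for (it in 1:40) {
      f <- resid(x, K_i)
      if (is.null(f)) return(NULL)
      if (sqrt(sum((f / sc)^2)) < 1e-9) {
        return(x)
      }
      J <- matrix(0, length(x), length(x))
      for (j in seq_along(x)) {
        d <- max(1e-6 * abs(x[j]), 1e-8)
        xp <- x; xm <- x; xp[j] <- x[j] + d; xm[j] <- x[j] - d
        fp <- resid(xp, K_i); fm <- resid(xm, K_i)
        if (is.null(fp) || is.null(fm)) return(NULL)
        J[, j] <- (fp - fm) / (2 * d)
      }
      s <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(s)) return(NULL)
      lam <- 1
      repeat {
        fn <- resid(x + lam * s, K_i)
        if (!is.null(fn) && sum((fn / sc)^2) <= sum((f / sc)^2) * (1 + 1e-9)) break
        lam <- lam / 2
        if (lam < 1e-6) return(NULL)
      }
      x <- x + lam * s
    }
    NULL
  }
  g0 <- gating_steady_states(p$V0, p)
  ## continuation in K_i from the physiological end downward
  x <- c(p$V0, g0$n_inf, p$Na_i0, if (buffered) p$K_e0)
  grid <- sort(K_i_grid, decreasing = TRUE)
  rows <- purrr::map(grid, function(K_i) {
    sol <- solve_pt(K_i, x)
    if (!is.null(sol)) x <<- sol
    tibble::tibble(K_i = K_i,
                   Na_i = if (is.null(sol)) NA_real_ else sol[3],
                   V = if (is.null(sol)) NA_real_ else sol[1],
                   converged = !is.null(sol))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$K_i)
}

#' Count nullcline intersections (fixed points) of a configuration
#'
#' Every intersection of the two ion nullcline curves is a full fixed point
#' of the model (voltage, gating and bath stationarity are imposed along
#' both curves, and the remaining chloride rate vanishes automatically by
#' charge conservation).  Because the curves are multivalued in the
#' `(K_i, Na_i)` projection, the count is computed robustly by enumerating
#' fixed points: Newton solves seeded from the physiological state, the
#' Donnan state, and interpolations between them, deduplicated by state
#' distance.
#'
#' @param params,config Model parameters and configuration.
#' @param n_seeds Number of interpolated seeds between the physiological
#'   and Donnan states.
#' @param curves Also return the two nullcline curves (for plotting).
#' @param K_i_grid Grid used when `curves = TRUE`.
#' @return List with `n_intersections`, `fixed_points` (list of
#'   `ion_fixed_point`), and optionally `curve_K`, `curve_Na`.
#' @export
nullcline_intersections <- function(params = ion_params(),
                                    config = ion_config(),
                                    n_seeds = 9, curves = FALSE,
                                    K_i_grid = seq(60, 132.8, by = 0.25)) {
  nm <- state_names(config)
  ref <- reference_state(params, config)
  dn <- donnan_state(params,
                     if (config$bath == "K_BATH")
                       ion_config(config$current_model, config$pump_model,
                                  config$chloride, config$gating, "CLOSED")
                     else config)
  dn_state <- dn$state
  if (config$bath == "K_BATH") {
    dn_state <- c(dn_state, K_e = unname(
      params$K_e0 + params$V_i / params$V_e * (params$K_i0 - dn$state[["K_i"]])))
  }
  fps <- list()
  for (a in seq(0, 1, length.out = n_seeds)) {
    g <- (1 - a) * ref[nm] + a * dn_state[nm]
    fp <- tryCatch(find_fixed_point(params, config, guess = g),
                   error = function(e) NULL)
    if (is.null(fp) || !fp$converged) next
    dup <- any(vapply(fps, function(z) {
      sqrt(sum(((z$state - fp$state) / .var_scales(nm))^2)) < 1e-4
    }, logical(1)))
    if (!dup) fps[[length(fps) + 1]] <- fp
  }
  out <- list(n_intersections = length(fps), fixed_points = fps)
  if (curves) {
    out$curve_K <- nullcline_curve(params, config, "K", K_i_grid)
    out$curve_Na <- nullcline_curve(params, config, "Na", K_i_grid)
  }
  out
}

#' Ionic excitability demonstration (potassium-bath coupled model)
#'
#' Runs the buffered default model through a stimulation protocol,
#' detects the free-energy-starvation transient, and computes the
#' nullcline projections of the closed and buffered systems.
#'
#' @param params Model parameters (Table-3 bath parameters by default).
#' @param protocol Stimulation protocol; default, the suprathreshold
#'   sodium-current pulse.
#' @param t_end Simulated time, ms.
#' @param nullclines Also compute nullcline intersection counts (slower).
#' @return List: `trajectory`, `events`, and (optionally) `nullclines`
#'   with intersection counts for the closed and buffered systems.
#' @export
excitability_run <- function(params = ion_params(),
                             protocol = protocol_na_pulse(),
                             t_end = 700e3, nullclines = FALSE) {
  cfg_b <- ion_config(bath = "K_BATH")
  tr <- simulate_model(params, cfg_b, protocol, t_end = t_end, n_out = 4000)
  ev <- detect_events(tr)
  out <- list(trajectory = tr, events = ev)
  if (nullclines) {
    out$nullclines <- list(
      closed = nullcline_intersections(params, ion_config()),
      buffered = nullcline_intersections(params, cfg_b)
    )
  }
  out
}

#' Deterministic fixture generation
#'
#' Writes small reference artefacts (trajectory CSVs at loose solver
#' settings, fixed-point JSONs for all 16 variant configurations) for
#' regression testing.  Fully deterministic given `seed`.
#'
#' @param seed Integer seed (used for the perturbation directions in the
#'   stability fixtures).
#' @param dir Output directory.
#' @return Invisible character vector of the files written.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("fixtures")) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- ion_params()
  grid <- variant_grid()
  for (i in seq_len(nrow(grid))) {
    for (gating in c("GATED", "LEAK_ONLY")) {
      cfg <- ion_config(current_model = grid$current_model[i],
                        pump_model = grid$pump_model[i],
                        chloride = grid$chloride[i], gating = gating)
      fp <- find_fixed_point(p, cfg)
      f <- file.path(dir, sprintf("fp_%d_%s.json", grid$variant[i], gating))
      jsonlite::write_json(list(
        config = unclass(cfg), state = as.list(fp$state),
        rho = fp$rho, residual = fp$residual,
        eigenvalues_re = Re(fp$eigenvalues),
        eigenvalues_im = Im(fp$eigenvalues),
        perturbation = as.list(stats::rnorm(length(fp$state), sd = 1e-3))
      ), f, digits = NA, auto_unbox = TRUE)
      files <- c(files, f)
    }
  }
  tr <- simulate_model(p, ion_config(), protocol_na_pulse(t_on = 1e3),
                       t_end = 20e3, n_out = 300, rtol = 1e-6, atol = 1e-8)
  f <- file.path(dir, "traj_pulse.csv")
  write_trajectory(tr, f)
  files <- c(files, f)
  invisible(files)
}
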