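## Stiff time integration under stimulation protocols, trajectory
## containers, event detection, and trajectory serialization.

#' Integrate a model configuration under a stimulation protocol
#'
#' Adaptive stiff integration (lsoda) of the reduced rate equations,
#' segmented exactly at the protocol discontinuities so that pulse edges are
#' step functions rather than events the solver might miss.  The returned
#' trajectory resolves both the millisecond membrane dynamics and the
#' hundred-second ion dynamics.
#'
#' @param params,config Model parameters and configuration.
#' @param protocol Stimulation protocol ([ion_protocol()]).
#' @param t_end End time, ms.
#' @param state0 Initial named state; defaults to the reference equilibrium.
#' @param n_out Approximate number of output rows (distributed over the
#'   protocol segments, with the stimulation window sampled densely enough
#'   to resolve spikes).
#' @param rtol,atol Solver tolerances.
#' @param rho Pump-rate override.
#' @return An `ion_trajectory`: a tibble with time (`t_ms`, and `t_s` for
#'   convenience), the independent state variables, the derived series
#'   (`Na_i`, ECS concentrations, reversal potentials, pump current), and
#'   attributes `params`, `config`, `protocol`, `solver`.
#' @examples
#' \donttest{
#' tr <- simulate_model(t_end = 2e3, n_out = 200)
#' }
#' @export
simulate_model <- function(params = ion_params(), config = ion_config(),
                           protocol = ion_protocol("NONE"), t_end = 1e3,
                           state0 = NULL, n_out = 2000,
                           rtol = 1e-8, atol = 1e-10, rho = NULL) {
  stopifnot(t_end > 0)
  p <- params
  if (is.null(state0)) state0 <- reference_state(p, config)
  nm <- state_names(config)
  state0 <- state0[nm]
  edges <- c(0, t_end)
  if (protocol$kind != "NONE") {
    edges <- sort(unique(c(0, protocol$t_on, protocol$t_off, t_end)))
    edges <- edges[edges >= 0 & edges <= t_end]
  }
  deriv <- function(t, y, parms) {
    names(y) <- nm
    list(unname(ion_rhs(t, y, p, config, protocol, rho = rho)))
  }
  segs <- list()
  n_steps <- 0
  y <- state0
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    # sample the (short) stimulation window densely, long windows sparsely
    frac <- (b - a) / t_end
    floor_i <- if (n_out >= 50) 50 else 2
    n_i <- max(floor_i, ceiling(n_out * max(frac, 0.25)))
    times <- seq(a, b, length.out = n_i)
    sol <- deSolve::ode(unname(y), times, deriv, NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 200000)
    n_steps <- n_steps + attr(sol, "istate")[3]
    seg <- as.data.frame(sol)
    names(seg) <- c("t_ms", nm)
    segs[[i]] <- if (i > 1) seg[-1, ] else seg
    y <- as.numeric(seg[nrow(seg), -1]); names(y) <- nm
  }
  tr <- tibble::as_tibble(do.call(rbind, segs))
  # derived series, recomputable bit-identically from the states
  der <- purrr::map(seq_len(nrow(tr)), function(i) {
    s <- as.numeric(tr[i, nm]); names(s) <- nm
    rho_t <- rho
    if (protocol$kind == "PUMP_OFF" &&
        tr$t_ms[i] >= protocol$t_on && tr$t_ms[i] < protocol$t_off) rho_t <- 0
    d <- derive_state(s, p, config, rho = rho_t)
    c(Na_i = d$Na_i, Na_e = d$Na_e, K_e = d$K_e, Cl_e = d$Cl_e,
      E_Na = d$E_Na, E_K = d$E_K, E_Cl = d$E_Cl, I_p = d$I_p)
  })
  der <- tibble::as_tibble(do.call(rbind, der))
  keep <- setdiff(names(der), nm)  # K_e may already be a state variable
  out <- dplyr::bind_cols(tr, der[keep])
  out <- dplyr::mutate(out, t_s = .data$t_ms / 1e3, .after = "t_ms")
  structure(out,
    class = c("ion_trajectory", class(out)),
    params = p, config = config, protocol = protocol,
    solver = list(method = "lsoda", rtol = rtol, atol = atol,
                  n_steps = unname(n_steps)))
}

#' Detect spikes, depolarisation events and the terminal regime
#'
#' Spikes are upward crossings of `spike_threshold` separated by at least
#' `refractory` ms.  A free-energy-starvation (FES) episode is a maximal
#' interval with `V` above `depol_threshold` lasting at least
#' `min_duration`.  The terminal state is classified `PHYSIOLOGICAL` when
#' the final `V` is within 2 mV of the resting potential and the final
#' `K_e` within 10 % of its reference, `FES` when the trajectory ends
#' depolarised, otherwise `UNRESOLVED`.
#'
#' @param traj An `ion_trajectory`.
#' @param spike_threshold Spike detection threshold, mV (default 0).
#' @param depol_threshold Sustained-depolarisation threshold, mV
#'   (default -40, midway between the resting and near-Donnan potentials).
#' @param min_duration Minimum FES duration, ms (default 5000).
#' @param refractory Minimum spike spacing, ms.
#' @return List of class `ion_events`: spike count/times, FES entry/exit
#'   times and duration (ms), terminal classification, and the
#'   post-recovery hyperpolarisation minimum (mV, `NA` if none).
#' @export
detect_events <- function(traj, spike_threshold = 0, depol_threshold = -40,
                          min_duration = 5000, refractory = 2) {
  stopifnot(inherits(traj, "ion_trajectory"))
  p <- attr(traj, "params")
  tt <- traj$t_ms; V <- traj$V
  up <- which(diff(V > spike_threshold) == 1)
  spike_times <- tt[up + 1]
  if (length(spike_times) > 1) {
    keep <- c(TRUE, diff(spike_times) >= refractory)
    spike_times <- spike_times[keep]
  }
  above <- V > depol_threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  fes_entry <- NA_real_; fes_exit <- NA_real_
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    dur <- tt[ends[k]] - tt[starts[k]]
    if (dur >= min_duration) {
      fes_entry <- tt[starts[k]]
      fes_exit <- if (ends[k] == length(tt)) NA_real_ else tt[ends[k]]
      break
    }
  }
  K_e_end <- traj$K_e[nrow(traj)]
  V_end <- V[length(V)]
  cls <- if (abs(V_end - p$V0) < 2 && abs(K_e_end - p$K_e0) < 0.1 * p$K_e0) {
    "PHYSIOLOGICAL"
  } else if (!is.na(fes_entry) && is.na(fes_exit) && V_end > depol_threshold) {
    "FES"
  } else {
    "UNRESOLVED"
  }
  hyper <- NA_real_
  if (!is.na(fes_exit)) hyper <- min(V[tt > fes_exit])
  structure(list(
    n_spikes = length(spike_times), spike_times = spike_times,
    fes_entry = fes_entry, fes_exit = fes_exit,
    fes_duration = if (!is.na(fes_entry) && !is.na(fes_exit))
      fes_exit - fes_entry else NA_real_,
    classification = cls, hyperpolarization_min = hyper,
    thresholds = c(spike = spike_threshold, depol = depol_threshold,
                   min_duration = min_duration)
  ), class = "ion_events")
}

#' @export
print.ion_events <- function(x, ...) {
  cat("<ion_events>", x$n_spikes, "spikes;",
      if (is.na(x$fes_entry)) "no FES episode" else
        sprintf("FES %.1f s -> %s", x$fes_entry / 1e3,
                if (is.na(x$fes_exit)) "end of run" else
                  sprintf("%.1f s (duration %.1f s)", x$fes_exit / 1e3,
                          x$fes_duration / 1e3)),
      "; terminal:", x$classification, "\n")
  invisible(x)
}

#' Write / read a trajectory
#'
#' CSV: one row per time point with a `# units:` comment header.  JSON:
#' metadata (configuration, solver) plus columnar arrays.  A write-read
#' round trip reproduces the numeric values to full double precision.
#'
#' @param traj An `ion_trajectory`.
#' @param path Output file path.
#' @param format `"CSV"` or `"JSON"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON" else "CSV"
  }
  format <- match.arg(format, c("CSV", "JSON"))
  df <- as.data.frame(traj)
  if (format == "CSV") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# units: t_ms ms; t_s s; V mV; concentrations mMol/l;",
                      " E_* mV; I_p uA/cm^2"), con)
    utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                     row.names = FALSE, quote = FALSE)
  } else {
    cfg <- attr(traj, "config")
    meta <- list(config = unclass(cfg), solver = attr(traj, "solver"),
                 protocol = unclass(attr(traj, "protocol")))
    jsonlite::write_json(list(meta = meta, columns = as.list(df)), path,
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON" else "CSV"
  }
  format <- match.arg(format, c("CSV", "JSON"))
  if (format == "CSV") {
    df <- utils::read.csv(path, comment.char = "#")
    tibble::as_tibble(df)
  } else {
    x <- jsonlite::fromJSON(path)
    tibble::as_tibble(as.data.frame(x$columns))
  }
}
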