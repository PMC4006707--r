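## Pseudo-arclength continuation of fixed points in the maximal pump rate,
## fold (LP) and Hopf (HB) detection, bistable-range extraction, and
## two-parameter sweeps over the geometry scalings.

# parameters continuation can act on; each rebuilds the evaluation context
.set_cont_param <- function(params, p_name, value) {
  if (p_name == "rho") return(list(params = params, rho = value))
  if (p_name %in% c("zeta", "omega")) {
    args <- stats::setNames(list(value), p_name)
    pr <- do.call(ion_params, c(args, list(rho_pump = params$rho_pump,
                                           Imax_B = params$Imax_B)))
    return(list(params = pr, rho = NULL))
  }
  stop("unsupported continuation parameter: ", p_name, call. = FALSE)
}

# eigen summary used along branches
.eig_info <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  cpx <- ev[abs(Im(ev)) > 1e-10]
  list(
    n_stable = sum(Re(ev) < 0),
    max_re = max(Re(ev)),
    max_re_complex = if (length(cpx)) max(Re(cpx)) else NA_real_,
    im_at_max = {
      i <- which.max(Re(ev)); abs(Im(ev[i]))
    },
    det = Re(prod(ev))
  )
}

#' Pseudo-arclength continuation of a fixed-point branch
#'
#' Secant predictor plus Newton corrector on the bordered system, with
#' per-variable scaling (100 mV, 100 mMol/l, 1) so the z-shaped branch is
#' traversed with comparable sensitivity in every direction.  Folds are
#' traversed; limit points (LP) are flagged where the Jacobian determinant
#' changes sign along the branch together with a reversal of the parameter
#' direction, Hopf points (HB) where the maximal real part over complex
#' eigenvalue pairs changes sign.  Both are refined by bisection in
#' arclength to a parameter tolerance of 1e-4 (relative to the parameter
#' scale).
#'
#' @param params,config Model parameters and configuration.
#' @param p_name Continuation parameter, currently `"rho"` (maximal pump
#'   current).
#' @param p_range Numeric length-2: continuation is stopped when the
#'   parameter leaves this interval.
#' @param start_fp Starting `ion_fixed_point` (converged) on the branch.
#' @param direction +1/-1: initial direction of the parameter.
#' @param ds0,ds_max Initial and maximal arclength step (scaled units).
#' @param max_steps Maximum number of continuation steps.
#' @param p_scale Parameter scale entering the arclength metric.
#' @return An `ion_branch`: tibble with the parameter, state variables,
#'   `max_re`, `n_stable`, `n_unstable`, `im_lead`, `det`; attribute
#'   `bifurcations` is a tibble of detected LP/HB points (type, parameter
#'   value, state, bracket width).
#' @export
trace_branch <- function(params = ion_params(), config = ion_config(),
                         p_name = "rho", p_range = c(0.02, 450),
                         start_fp = NULL, direction = -1,
                         ds0 = 0.01, ds_max = 0.08, max_steps = 4000,
                         p_scale = 5, stop_at = NULL) {
  nm <- state_names(config)
  rs <- .res_scales(nm)
  vs <- .var_scales(nm)
  if (is.null(start_fp)) start_fp <- find_fixed_point(params, config)
  if (!start_fp$converged) stop("start_fp not converged", call. = FALSE)

  eval_rhs <- function(y, pv) {
    ctx <- .set_cont_param(params, p_name, pv)
    ion_rhs(0, y, ctx$params, config, rho = ctx$rho)
  }
  eval_jac <- function(y, pv) {
    ctx <- .set_cont_param(params, p_name, pv)
    rhs_jacobian(y, ctx$params, config, rho = ctx$rho)
  }
  usc <- function(u) c(u[seq_along(nm)] / vs, u[length(u)] / p_scale)

  corrector <- function(u, tang, u_anchor) {
    for (it in 1:12) {
      y <- u[seq_along(nm)]; names(y) <- nm
      pv <- u[length(u)]
      f <- tryCatch(eval_rhs(y, pv), error = function(e) NULL)
      if (is.null(f)) return(list(conv = FALSE))
      g <- sum((usc(u) - usc(u_anchor)) * tang)
      FF <- c(f / rs, g)
      if (sqrt(sum(FF^2)) < 1e-10) return(list(u = u, conv = TRUE, it = it))
      J <- tryCatch(eval_jac(y, pv), error = function(e) NULL)
      if (is.null(J)) return(list(conv = FALSE))
      dp <- 1e-7 * max(1, abs(pv))
      fr <- (eval_rhs(y, pv + dp) - eval_rhs(y, pv - dp)) / (2 * dp)
      A <- rbind(cbind(sweep(J, 1, rs, "/"), fr / rs),
                 c(tang[seq_along(nm)] / vs, tang[length(tang)] / p_scale))
      s <- tryCatch(solve(A, -FF), error = function(e) NULL)
      if (is.null(s)) return(list(conv = FALSE))
      u <- u + s
    }
    list(conv = FALSE)
  }

  u <- c(unname(start_fp$state[nm]), start_fp$rho)
  u_prev <- NULL
  ds <- ds0
  rows <- vector("list", max_steps)
  us <- vector("list", max_steps)
  k <- 0
  status <- "max_steps"
  while (k < max_steps) {
    tang <- if (is.null(u_prev)) {
      c(rep(0, length(nm)), direction)
    } else {
      usc(u) - usc(u_prev)
    }
    tang <- tang / sqrt(sum(tang^2))
    pred_sc <- usc(u) + ds * tang
    u_pred <- c(pred_sc[seq_along(nm)] * vs, pred_sc[length(pred_sc)] * p_scale)
    cr <- corrector(u_pred, tang, u_pred)
    # reject non-advancing solutions (would retrace the branch) and
    # over-long jumps (would hop onto a different branch near a fold)
    if (cr$conv) {
      adv <- sum((usc(cr$u) - usc(u)) * tang)
      dist <- sqrt(sum((usc(cr$u) - usc(u))^2))
      # first step has only the crude parameter-direction tangent, so its
      # arclength estimate can be well below the true distance
      cap <- if (is.null(u_prev)) 25 * ds else 5 * ds
      if (adv <= 0 || dist > cap) cr$conv <- FALSE
    }
    if (!cr$conv) {
      ds <- ds / 2
      if (ds < 1e-9) { status <- "step_underflow"; break }
      next
    }
    u_prev <- u
    u <- cr$u
    k <- k + 1
    y <- u[seq_along(nm)]; names(y) <- nm
    ei <- tryCatch(.eig_info(eval_jac(y, u[length(u)])),
                   error = function(e) NULL)
    if (is.null(ei)) { status <- "domain_boundary"; u <- u_prev; break }
    rows[[k]] <- stats::setNames(
      c(u[length(u)], y, ei$max_re, ei$n_stable, ei$im_at_max, ei$det,
        ei$max_re_complex),
      c(p_name, nm, "max_re", "n_stable", "im_lead", "det", "max_re_cpx"))
    us[[k]] <- u
    if (cr$it <= 4) ds <- min(ds * 1.3, ds_max)
    if (u[length(u)] > max(p_range) || u[length(u)] < min(p_range)) {
      status <- "left_range"; break
    }
    if (!is.null(stop_at) && k > 1) {
      if (!exists("stop_in", inherits = FALSE)) stop_in <- NA_integer_
      r0 <- rows[[k - 1]]; r1 <- rows[[k]]
      hb_cross <- !is.na(r0[["max_re_cpx"]]) && !is.na(r1[["max_re_cpx"]]) &&
        r0[["max_re_cpx"]] * r1[["max_re_cpx"]] < 0
      lp_cross <- r0[["det"]] * r1[["det"]] < 0
      if (is.na(stop_in) &&
          ((stop_at == "HB" && hb_cross) || (stop_at == "LP" && lp_cross))) {
        stop_in <- 4L  # a few more steps so folds show their reversal
      }
      if (!is.na(stop_in)) {
        stop_in <- stop_in - 1L
        if (stop_in <= 0L) { status <- paste0("stopped_at_", stop_at); break }
      }
    }
  }
  if (k == 0) {
    br <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(nm) + 6),
      c(p_name, nm, "max_re", "n_stable", "im_lead", "det", "max_re_cpx")))
    return(structure(br, class = c("ion_branch", class(br)),
                     bifurcations = tibble::tibble(
                       type = character(), !!p_name := numeric(),
                       V = numeric(), bracket = numeric()),
                     p_name = p_name, config = config, status = status))
  }
  br <- tibble::as_tibble(do.call(rbind, rows[seq_len(k)]))
  ## --- bifurcation detection ----------------------------------------
  bifs <- list()
  pv <- br[[p_name]]
  dirs <- sign(c(diff(pv), utils::tail(diff(pv), 1)))
  refine <- function(u0, u1, test_fn) {
    # bisection in arclength between consecutive branch points
    for (i in 1:40) {
      tang <- usc(u1) - usc(u0); tang <- tang / sqrt(sum(tang^2))
      um <- (u0 + u1) / 2
      cr <- corrector(um, tang, um)
      if (!cr$conv) break
      if (sign(test_fn(cr$u)) == sign(test_fn(u0))) u0 <- cr$u else u1 <- cr$u
      if (abs(u1[length(u1)] - u0[length(u0)]) < 1e-4 &&
          sqrt(sum((usc(u1) - usc(u0))^2)) < 1e-6) break
    }
    list(u = (u0 + u1) / 2,
         width = abs(u1[length(u1)] - u0[length(u0)]))
  }
  tf_det <- function(u) {
    y <- u[seq_along(nm)]; names(y) <- nm
    .eig_info(eval_jac(y, u[length(u)]))$det
  }
  tf_hopf <- function(u) {
    y <- u[seq_along(nm)]; names(y) <- nm
    v <- .eig_info(eval_jac(y, u[length(u)]))$max_re_complex
    if (is.na(v)) -1 else v
  }
  if (k > 2) {
    det_v <- br$det
    cpx_v <- ifelse(is.na(br$max_re_cpx), -1, br$max_re_cpx)
    for (i in seq_len(k - 1)) {
      if (det_v[i] * det_v[i + 1] < 0) {
        # distinguish LP (parameter reversal nearby) from a real crossing
        nearby <- dirs[max(1, i - 2):min(k - 1, i + 2)]
        is_fold <- length(unique(nearby[nearby != 0])) > 1
        r <- refine(us[[i]], us[[i + 1]], tf_det)
        y <- r$u[seq_along(nm)]; names(y) <- nm
        ei_r <- .eig_info(eval_jac(y, r$u[length(r$u)]))
        bifs[[length(bifs) + 1]] <- tibble::tibble(
          type = if (is_fold) "LP" else "NEUTRAL",
          !!p_name := r$u[length(r$u)],
          V = y[["V"]], bracket = r$width,
          re_crossing = {
            ev <- eigen(eval_jac(y, r$u[length(r$u)]),
                        only.values = TRUE)$values
            Re(ev[which.min(abs(Re(ev)))])
          },
          im_crossing = {
            ev <- eigen(eval_jac(y, r$u[length(r$u)]),
                        only.values = TRUE)$values
            abs(Im(ev[which.min(abs(Re(ev)))]))
          })
      }
      if (cpx_v[i] * cpx_v[i + 1] < 0 && !is.na(br$max_re_cpx[i]) &&
          !is.na(br$max_re_cpx[i + 1])) {
        r <- refine(us[[i]], us[[i + 1]], tf_hopf)
        y <- r$u[seq_along(nm)]; names(y) <- nm
        bifs[[length(bifs) + 1]] <- tibble::tibble(
          type = "HB", !!p_name := r$u[length(r$u)],
          V = y[["V"]], bracket = r$width,
          re_crossing = NA_real_, im_crossing = {
            ev <- eigen(eval_jac(y, r$u[length(r$u)]),
                        only.values = TRUE)$values
            cp <- ev[abs(Im(ev)) > 1e-10]
            if (length(cp)) abs(Im(cp[which.min(abs(Re(cp)))])) else 0
          })
      }
    }
  }
  bifs <- if (length(bifs)) dplyr::bind_rows(bifs) else
    tibble::tibble(type = character(), !!p_name := numeric(),
                   V = numeric(), bracket = numeric(),
                   re_crossing = numeric(), im_crossing = numeric())
  structure(br, class = c("ion_branch", class(br)),
            bifurcations = bifs, p_name = p_name, config = config,
            status = status)
}

#' Bifurcations detected on a branch
#' @param branch An `ion_branch`.
#' @return Tibble of LP/HB points.
#' @export
bifurcations <- function(branch) attr(branch, "bifurcations")

#' Bistable range of pump rates
#'
#' Lower edge: the limit point (LP) at which the physiological fixed point
#' is annihilated when the pump rate is reduced (minimal physiological pump
#' rate).  Upper edge: the Hopf point at which the depolarised
#' (free-energy-starved) fixed point loses stability when the pump rate is
#' increased (minimal recovery pump rate).  Leak-only configurations have a
#' single monotone branch with neither bifurcation and yield a
#' `monostable = TRUE` result.
#'
#' @param params,config Model parameters and configuration.
#' @param rho_max Upper bound of the recovery search.
#' @return List: `rho_min_phys`, `rho_recovery` (uA/cm^2, `NA` when
#'   absent), `monostable`, and the two traced branches.
#' @export
bistable_range <- function(params = ion_params(), config = ion_config(),
                           rho_max = 400) {
  rho0 <- if (config$pump_model == "A") params$rho_pump else params$Imax_B
  if (config$gating == "LEAK_ONLY") {
    ## single monotone branch: trace from the physiological point towards
    ## zero pump rate; no LP/HB exists and the branch ends near the Donnan
    ## state.
    fp <- find_fixed_point(params, config)
    low <- trace_branch(params, config, p_range = c(1e-4, rho0 * 1.05),
                        start_fp = fp, direction = -1, max_steps = 1500)
    return(list(rho_min_phys = NA_real_, rho_recovery = NA_real_,
                monostable = nrow(bifurcations(low)) == 0,
                branch_low = low, branch_up = NULL))
  }
  ## physiological branch downward -> LP
  fp <- find_fixed_point(params, config)
  low <- trace_branch(params, config, p_range = c(0.002, rho0 * 1.05),
                      start_fp = fp, direction = -1, max_steps = 1500,
                      stop_at = "LP")
  lp <- dplyr::filter(bifurcations(low), .data$type == "LP")
  rho_min <- if (nrow(lp)) min(lp$rho) else NA_real_
  ## depolarised branch from the Donnan state upward -> HB
  dn <- donnan_state(params, config)
  up <- trace_branch(params, config, p_range = c(-0.05, rho_max),
                     start_fp = dn, direction = +1, max_steps = 4000,
                     ds0 = 0.005, stop_at = "HB")
  hb <- dplyr::filter(bifurcations(up), .data$type == "HB")
  ## the recovery rate is the first Hopf destabilising the stable branch
  rho_rec <- if (nrow(hb)) min(hb$rho) else NA_real_
  monostable <- is.na(rho_min) || is.na(rho_rec)
  list(rho_min_phys = rho_min, rho_recovery = rho_rec,
       monostable = monostable, branch_low = low, branch_up = up)
}

#' Brute-force oracle for the bistable range
#'
#' Independent of the continuation machinery: scans a pump-rate grid,
#' solves for the physiological and depolarised fixed points by Newton
#' iteration seeded from their reference shapes, checks their existence and
#' linear stability, and brackets the edges by bisection.
#'
#' @param params,config Model parameters and configuration.
#' @param rho_lo,rho_hi Scan interval.
#' @param n_grid Grid size of the initial scan.
#' @param refine_iter Bisection refinements of each edge.
#' @return List `rho_min_phys`, `rho_recovery` as in [bistable_range()].
#' @export
bistable_range_scan <- function(params = ion_params(), config = ion_config(),
                                rho_lo = 0.02, rho_hi = 120, n_grid = 25,
                                refine_iter = 30) {
  phys_ref <- reference_state(params, config)
  dn <- donnan_state(params, config)
  phys_ok <- function(rho) {
    fp <- find_fixed_point(params, config, guess = phys_ref, rho = rho)
    fp$converged && fp$n_unstable == 0 &&
      abs(fp$state[["V"]] - params$V0) < 15
  }
  dep_state <- dn$state
  dep_ok <- function(rho) {
    fp <- find_fixed_point(params, config, guess = dep_state, rho = rho)
    if (!fp$converged || fp$state[["V"]] < -45) return(NA)
    dep_state <<- fp$state  # warm start along the scan
    fp$n_unstable == 0
  }
  bisect <- function(f, lo, hi, target_lo) {
    # f TRUE on one side; returns edge
    for (i in seq_len(refine_iter)) {
      mid <- (lo + hi) / 2
      v <- f(mid)
      if (is.na(v)) v <- FALSE
      if (v == target_lo) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-4 * max(1, hi)) break
    }
    (lo + hi) / 2
  }
  grid <- exp(seq(log(rho_lo), log(rho_hi), length.out = n_grid))
  ex <- vapply(grid, phys_ok, logical(1))
  rho_min <- if (any(ex) && !all(ex)) {
    i <- which(ex)[1]
    if (i == 1) NA_real_ else bisect(phys_ok, grid[i - 1], grid[i], FALSE)
  } else NA_real_
  st <- vapply(grid, function(r) isTRUE(dep_ok(r)), logical(1))
  dep_state <- dn$state
  rho_rec <- if (any(st) && !all(st)) {
    i <- utils::tail(which(st), 1)
    if (i == length(grid)) NA_real_ else {
      dep_state <- dn$state
      for (g in grid[seq_len(i)]) dep_ok(g)  # warm start up to the edge
      bisect(function(r) isTRUE(dep_ok(r)), grid[i], grid[i + 1], TRUE)
    }
  } else NA_real_
  list(rho_min_phys = rho_min, rho_recovery = rho_rec)
}

#' Two-parameter continuation of a bifurcation locus
#'
#' Follows the location of a detected bifurcation (the physiological-branch
#' LP or the recovery HB) across a second parameter (`zeta`, the
#' dimensionless membrane-surface scale, or `omega`, the extracellular
#' volume fraction).  Implemented by the re-fetch strategy declared in the
#' metadata: at each value of the second parameter the relevant
#' one-parameter detection is re-run (warm-started from the neighbouring
#' value) rather than continuing the bordered codimension-1 system.
#'
#' @param params,config Model parameters and configuration.
#' @param bif `"LP"` (minimal physiological rate) or `"HB"` (recovery
#'   rate).
#' @param second_param `"zeta"` or `"omega"`.
#' @param values Grid of second-parameter values.
#' @param rho_max Search cap for the HB.
#' @return Tibble with columns `second_param`, `value`, `rho`; attribute
#'   `strategy = "refetch"`.
#' @export
two_parameter_curve <- function(params = ion_params(), config = ion_config(),
                                bif = c("LP", "HB"),
                                second_param = c("zeta", "omega"),
                                values = NULL, rho_max = 400) {
  bif <- match.arg(bif)
  second_param <- match.arg(second_param)
  if (is.null(values)) {
    values <- if (second_param == "zeta") {
      exp(seq(log(0.1), log(10), length.out = 7))
    } else {
      c(0.02, 0.04, 0.1, 0.25, 0.4, 0.5)
    }
  }
  rows <- purrr::map(values, function(v) {
    args <- stats::setNames(list(v), second_param)
    pr <- do.call(ion_params, c(args, list(
      rho_pump = params$rho_pump, Imax_B = params$Imax_B)))
    r <- tryCatch({
      if (bif == "LP") {
        fp <- find_fixed_point(pr, config)
        b <- trace_branch(pr, config,
                          p_range = c(0.002, fp$rho * 1.05),
                          start_fp = fp, direction = -1, max_steps = 1500,
                          stop_at = "LP")
        lp <- dplyr::filter(bifurcations(b), .data$type == "LP")
        if (nrow(lp)) min(lp$rho) else NA_real_
      } else {
        dn <- donnan_state(pr, config)
        b <- trace_branch(pr, config, p_range = c(-0.05, rho_max),
                          start_fp = dn, direction = +1, max_steps = 4000,
                          ds0 = 0.005, stop_at = "HB")
        hb <- dplyr::filter(bifurcations(b), .data$type == "HB")
        if (nrow(hb)) min(hb$rho) else NA_real_
      }
    }, error = function(e) NA_real_)
    tibble::tibble(second_param = second_param, value = v, rho = r)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "strategy") <- "refetch"
  attr(out, "bif") <- bif
  out
}
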