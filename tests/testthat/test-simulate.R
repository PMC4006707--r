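p0 <- ion_params()
cfg0 <- ion_config()

test_that("unstimulated run from equilibrium is stationary for 1000 s", {
  tr <- simulate_model(p0, cfg0, t_end = 1e6, n_out = 200)
  expect_lt(max(abs(tr$V - p0$V0)), 0.1)
  expect_lt(max(abs(tr$K_i - p0$K_i0)), 0.01)
})

test_that("suprathreshold pulse spikes into the depolarized fixed point and
           pump-off reaches the same point", {
  tra <- fig1a_trajectory()
  eva <- detect_events(tra)
  expect_gt(eva$n_spikes, 5)           # spiking during the pulse
  expect_identical(eva$classification, "FES")
  expect_true(is.na(eva$fes_exit))     # never repolarises (bistable)
  fpd <- depolarized_fp()
  expect_true(fpd$converged)
  expect_identical(fpd$n_unstable, 0L)
  expect_gt(fpd$state[["V"]], -30)     # strongly depolarised
  # ion gradients nearly collapsed: all reversal potentials close to V
  td <- tidy(fpd)
  for (E in c("E_Na", "E_K", "E_Cl")) {
    expect_lt(abs(td$value[td$variable == E] - fpd$state[["V"]]), 15)
  }
  # pump-off protocol terminates in the same fixed point
  trb <- fig1b_trajectory()
  nm <- c("V", "n", "K_i", "Cl_i")
  yb <- as.numeric(trb[nrow(trb), nm]); names(yb) <- nm
  fpb <- find_fixed_point(guess = yb)
  for (v in nm) {
    tol <- if (v %in% c("K_i", "Cl_i")) 0.1 else 0.1
    expect_lt(abs(fpb$state[[v]] - fpd$state[[v]]), tol)
  }
})

test_that("terminal state is insensitive to halving the tolerances", {
  run <- function(rtol, atol) {
    tr <- simulate_model(p0, cfg0,
                         protocol_na_pulse(150, t_on = 2e3, duration = 1e3),
                         t_end = 150e3, n_out = 400,
                         rtol = rtol, atol = atol)
    tr$V[nrow(tr)]
  }
  expect_lt(abs(run(1e-8, 1e-10) - run(5e-9, 5e-11)), 0.1)
})

test_that("the conserved charge-potential combination drifts below 1e-6 of
           its scale over 1000 s (unreduced system)", {
  y0 <- c(V = -66, n = 0.07, Na_i = 27.5, K_i = 130.6, Cl_i = 9.7)
  deriv <- function(t, y, parms) {
    list(unname(ionshift:::ion_rhs_full(t, y, p0, cfg0)))
  }
  out <- deSolve::ode(y0, seq(0, 1e6, length.out = 50), deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  cons <- apply(out[, -1], 1, function(r) {
    conserved_charge(stats::setNames(r, colnames(out)[-1]), p0, cfg0)
  })
  expect_lt(max(abs(cons - cons[1])) / abs(cons[1]), 1e-6)
  # per-species mass conservation along the same run
  totK <- p0$V_i * out[, "K_i"] +
    p0$V_e * (p0$K_e0 + p0$V_i / p0$V_e * (p0$K_i0 - out[, "K_i"]))
  expect_lt(diff(range(totK)) / totK[1], 1e-12)
})

test_that("trajectory serialization round-trips and has unit headers", {
  tr <- simulate_model(p0, cfg0, t_end = 100, n_out = 3)
  fcsv <- tempfile(fileext = ".csv")
  write_trajectory(tr, fcsv)
  back <- read_trajectory(fcsv)
  expect_equal(back$V, tr$V, tolerance = 1e-15)
  expect_equal(back$K_i, tr$K_i, tolerance = 1e-15)
  expect_true(all(c("t_ms", "V", "n", "K_i", "Cl_i") %in% names(back)))
  lines <- readLines(fcsv)
  expect_match(lines[1], "units")
  # 3 time points -> comment + header + 3 data rows
  expect_length(lines, 5)
  fjson <- tempfile(fileext = ".json")
  write_trajectory(tr, fjson)
  backj <- read_trajectory(fjson)
  expect_equal(backj$V, tr$V, tolerance = 1e-15)
})

test_that("event detection: quiescent runs have no spikes and no FES", {
  tr <- simulate_model(p0, cfg0, t_end = 20e3, n_out = 500)
  ev <- detect_events(tr)
  expect_identical(ev$n_spikes, 0L)
  expect_true(is.na(ev$fes_entry))
  expect_identical(ev$classification, "PHYSIOLOGICAL")
})
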