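p0 <- ion_params()
cfg0 <- ion_config()
s0 <- reference_state(p0, cfg0)

test_that("chloride current vanishes at the reference equilibrium", {
  I <- membrane_currents(s0, p0, cfg0)
  # V0 = E_Cl by construction of the reference concentrations
  expect_lt(abs(I[["I_Cl"]]), 1e-3)
  # chloride off: identically zero
  I2 <- membrane_currents(s0[c("V", "n", "K_i")], p0,
                          ion_config(chloride = FALSE))
  expect_identical(I2[["I_Cl"]], 0)
})

test_that("GHK currents vanish exactly at each species' Nernst potential", {
  p <- p0
  for (sp in list(list(z = 1, ci = 27, ce = 120, P = p$P_Na_leak),
                  list(z = 1, ci = 130.99, ce = 4, P = p$P_K_leak),
                  list(z = -1, ci = 9.66, ce = 124, P = p$P_Cl_leak))) {
    E <- nernst_potential(sp$z, sp$ce, sp$ci, p$phi_T)
    I <- ionshift:::.ghk_current(sp$P, sp$z, E, sp$ci, sp$ce, p$phi_T)
    expect_lt(abs(I), 1e-10)
    # and is monotonically increasing in V through the reversal
    Ip <- ionshift:::.ghk_current(sp$P, sp$z, E + 5, sp$ci, sp$ce, p$phi_T)
    Im <- ionshift:::.ghk_current(sp$P, sp$z, E - 5, sp$ci, sp$ce, p$phi_T)
    expect_gt(Ip, 0); expect_lt(Im, 0)
  }
})

test_that("pump current saturates, increases in Na_i and K_e, never NaN", {
  for (pm in c("A", "B")) {
    cap <- if (pm == "A") p0$rho_pump else p0$Imax_B
    f <- function(Na, Ke) ionshift:::.pump_current_raw(Na, Ke, cap, pm)
    expect_identical(ionshift:::.pump_current_raw(27, 4, 0, pm), 0)
    expect_equal(f(1e6, 1e6), cap, tolerance = 1e-4)
    grid <- expand.grid(Na = c(5, 27, 60, 150), Ke = c(0.5, 4, 40))
    v <- with(grid, f(Na, Ke))
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= cap))
    # monotone in each argument (strictly, away from the clamped tails)
    expect_true(all(diff(f(seq(1, 100, by = 1), 4)) > 0))
    expect_true(all(diff(f(27, seq(0.2, 20, by = 0.2))) > 0))
    expect_true(all(diff(f(seq(1, 500, by = 1), 4)) >= 0))
    # extreme arguments are clamped, not NaN
    expect_true(is.finite(f(-1e4, 1e9)))
  }
})

test_that("pump A balances the equilibrium Na and K currents at 3:2", {
  I <- membrane_currents(s0, p0, cfg0)
  Ip <- pump_current(s0, p0, cfg0)
  expect_equal(3 * Ip, -I[["I_Na"]], tolerance = 0.02)
  expect_equal(2 * Ip, I[["I_K"]], tolerance = 0.02)
})

test_that("calibrated pump B retains the default fixed point", {
  expect_equal(calibrate_pump_B(), p0$Imax_B, tolerance = 1e-4)
  expect_gt(p0$Imax_B, p0$rho_pump)       # slightly higher than pump A's
  expect_lt(p0$Imax_B, 1.2 * p0$rho_pump) # but in the same range
  fpB <- find_fixed_point(p0, ion_config(pump_model = "B"))
  expect_equal(fpB$state[["V"]], -68, tolerance = 0.5 / 68)
})

test_that("bath term is linear and restores K_e towards K_reg", {
  expect_identical(bath_term(4, p0), 0)
  expect_equal(bath_term(5, p0), -p0$lambda_bath)
  p2 <- ion_params(lambda_bath = 2 * p0$lambda_bath)
  expect_equal(bath_term(7, p2), 2 * bath_term(7, p0))
  expect_gt(bath_term(2, p0), 0)
})

test_that("mass conservation maps ICS to ECS with the 3:1 volume lever", {
  e <- ecs_from_ics(s0, p0, cfg0)
  expect_equal(unname(e), c(p0$Na_e0, p0$K_e0, p0$Cl_e0), tolerance = 1e-12)
  s1 <- s0; s1[["K_i"]] <- s0[["K_i"]] - 1
  e1 <- ecs_from_ics(s1, p0, cfg0)
  expect_equal(e1[["K_e"]] - p0$K_e0, 3, tolerance = 1e-12)
  # driving K_i far down overdraws the ECS potassium: hard error with name
  s2 <- s0; s2[["Cl_i"]] <- 80
  expect_error(ecs_from_ics(s2, p0, cfg0), "Cl_e")
})

test_that("charge constraint reproduces electroneutral exchange and its
           voltage term is tiny", {
  expect_equal(na_from_charge_constraint(s0, p0, cfg0), 27, tolerance = 1e-12)
  s1 <- s0; s1[["K_i"]] <- s0[["K_i"]] - 1
  expect_equal(na_from_charge_constraint(s1, p0, cfg0), 28, tolerance = 1e-12)
  # a 100 mV excursion moves Na_i by gamma' C_m / V_i * 100 ~ 4.4e-3 mM
  s2 <- s0; s2[["V"]] <- s0[["V"]] + 100
  dNa <- na_from_charge_constraint(s2, p0, cfg0) - 27
  expect_equal(dNa, 10 * conversion_gamma(p0) * p0$C_m / p0$V_i * 100,
               tolerance = 1e-10)
  expect_lt(abs(dNa), 0.01)
  # chloride-off specialisation drops the Cl term
  cfg2 <- ion_config(chloride = FALSE)
  s3 <- s0[c("V", "n", "K_i")]; s3[["K_i"]] <- s3[["K_i"]] + 2
  expect_equal(na_from_charge_constraint(s3, p0, cfg2), 25, tolerance = 1e-12)
})
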