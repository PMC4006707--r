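test_that("Nernst potentials reproduce the reference values", {
  expect_equal(nernst_potential(+1, 120, 27), 39.74, tolerance = 0.01 / 39.74)
  expect_equal(nernst_potential(+1, 4, 130.99), -92.94,
               tolerance = 0.01 / 92.94)
  expect_equal(nernst_potential(-1, 124, 9.66), -68, tolerance = 0.01 / 68)
  # equal concentrations give zero for either valence
  expect_identical(nernst_potential(+1, 10, 10), 0)
  expect_identical(nernst_potential(-1, 10, 10), 0)
  expect_error(nernst_potential(+1, -1, 10), "positive")
  expect_error(nernst_potential(+2, 10, 10), "valence")
})

test_that("conversion factor and volume arithmetic match the geometry", {
  p <- ion_params()
  expect_equal(conversion_gamma(p), 9.556e-3, tolerance = 1e-4)
  expect_equal(p$omega, 720 / 2880)
  expect_equal(omega_from_tissue(0.2, 0.4, 0.4), 1 / 3)
  # omega override redistributes the fixed total volume
  p2 <- ion_params(omega = 0.1)
  expect_equal(p2$V_e / (p2$V_i + p2$V_e), 0.1)
  expect_equal(p2$V_i + p2$V_e, 2880)
})

test_that("parameter validation rejects unphysical input and label swaps", {
  expect_error(ion_params(C_m = -1), "positive")
  expect_error(ion_params(omega = 1.5), "omega")
  expect_error(ion_params(nonsense = 1), "unknown parameter")
  # swapped ECS/ICS assignment fails the printed-Nernst-potential guard
  expect_error(ion_params(Na_i0 = 120, Na_e0 = 27, K_i0 = 4, K_e0 = 130.99,
                          Cl_i0 = 124, Cl_e0 = 9.66),
               "Nernst")
})

test_that("all 32 variant configurations are constructible", {
  n <- 0L
  for (cm in c("NERNST", "GHK")) for (pm in c("A", "B"))
    for (cl in c(TRUE, FALSE)) for (gt in c("GATED", "LEAK_ONLY"))
      for (ba in c("CLOSED", "K_BATH")) {
        cfg <- ion_config(cm, pm, cl, gt, ba)
        expect_s3_class(cfg, "ion_config")
        expect_type(state_names <- ionshift:::state_names(cfg), "character")
        n <- n + 1L
      }
  expect_identical(n, 32L)
  # default model
  cfg <- ion_config()
  expect_identical(cfg$current_model, "NERNST")
  expect_identical(cfg$pump_model, "A")
  expect_true(cfg$chloride)
  expect_identical(cfg$gating, "GATED")
  expect_identical(cfg$bath, "CLOSED")
})

test_that("protocols validate their windows", {
  expect_error(ion_protocol("NA_PULSE", t_on = 5, t_off = 1))
  pr <- protocol_na_pulse(amplitude = 150, t_on = 1e3, duration = 500)
  expect_identical(pr$t_off - pr$t_on, 500)
  expect_error(ion_protocol("NA_PULSE", t_on = 0, t_off = 1,
                            amplitude = Inf))
})

test_that("conductance-to-permeability conversion shares one factor per
           species and GHK leak currents match Nernst at calibration", {
  conv <- permeability_from_conductance(
    c(0.0175, 100, 0.05, 40, 0.05), c("Na", "Na", "K", "K", "Cl"))
  # common conversion factor for leak and gated channels of a species
  expect_equal(conv$conversion[1], conv$conversion[2], tolerance = 1e-12)
  expect_equal(conv$conversion[3], conv$conversion[4], tolerance = 1e-12)
  # ratio identity P_gated / P_leak = g_gated / g_leak
  expect_equal(conv$permeability[2] / conv$permeability[1], 100 / 0.0175,
               tolerance = 1e-10)
  expect_equal(conv$permeability[4] / conv$permeability[3], 40 / 0.05,
               tolerance = 1e-10)
  # calibration condition: each GHK leak current equals its Nernst
  # counterpart at the reference equilibrium to within 1 %
  p <- ion_params()
  s <- reference_state(p, ion_config())
  IN <- membrane_currents(s, p, ion_config())
  IG <- membrane_currents(s, p, ion_config(current_model = "GHK"))
  expect_equal(IG[["I_Na"]], IN[["I_Na"]], tolerance = 0.01)
  expect_equal(IG[["I_K"]], IN[["I_K"]], tolerance = 0.01)
  expect_lt(abs(IG[["I_Cl"]] - IN[["I_Cl"]]), 1e-3)
})

test_that("an empty JSON configuration reproduces the default model", {
  f <- tempfile(fileext = ".json")
  writeLines("{}", f)
  pc <- read_ion_config(f)
  expect_equal(pc$params$rho_pump, 5.25)
  expect_identical(pc$config$current_model, "NERNST")
  f2 <- tempfile(fileext = ".json")
  writeLines('{"params": {"rho_pump": 8}, "config": {"pump_model": "B"}}', f2)
  pc2 <- read_ion_config(f2)
  expect_equal(pc2$params$rho_pump, 8)
  expect_identical(pc2$config$pump_model, "B")
})
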