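test_that("all gated variants are bistable, no leak-only variant is, and
           pump A always tolerates lower pump rates than pump B", {
  vs <- default_variant_sweep()
  expect_identical(nrow(vs), 8L)
  expect_true(all(vs$bistable))
  expect_true(all(vs$leak_monostable))
  expect_true(all(vs$ratio_min > 0 & vs$ratio_recovery > 0))
  expect_lt(max(vs$rho_min_phys[vs$pump_model == "A"]),
            min(vs$rho_min_phys[vs$pump_model == "B"]))
  # every gated variant's band contains the default pump rate
  expect_true(all(vs$rho_min_phys < 5.25 & vs$rho_recovery > 5.25))
})

test_that("recovery pump rates span several-fold to far above the default", {
  vs <- default_variant_sweep()
  expect_lt(min(vs$ratio_recovery), 8)
  expect_gt(max(vs$ratio_recovery), 30)
})

test_that("the physiological fixed point is unchanged by chloride", {
  p <- ion_params()
  for (cm in c("NERNST", "GHK")) for (pm in c("A", "B")) {
    f1 <- find_fixed_point(p, ion_config(cm, pm, chloride = TRUE))
    f2 <- find_fixed_point(p, ion_config(cm, pm, chloride = FALSE))
    # identical up to the tiny chloride re-equilibration carried by the
    # charge constraint (order gamma' C_m / V_i)
    expect_lt(abs(f1$state[["V"]] - f2$state[["V"]]), 0.01)
    expect_lt(abs(f1$state[["K_i"]] - f2$state[["K_i"]]), 0.01)
  }
})

test_that("geometry sweep reproduces the anchor values and the shrunken-ECS
           regime keeps recovery far above twice the baseline", {
  oc <- cached("omega_curve", two_parameter_curve(
    bif = "HB", second_param = "omega", values = c(0.04, 0.1, 0.25, 0.5)))
  r04 <- oc$rho[oc$value == 0.04]
  r25 <- oc$rho[oc$value == 0.25]
  expect_lt(r04, r25)           # shrunken ECS reduces the recovery rate
  expect_gt(r04, 2 * 5.25)      # but it stays well above 2x baseline
})

test_that("nullcline counting: three intersections closed, one buffered,
           and the curves satisfy their defining conditions", {
  ni_c <- cached("null_closed", nullcline_intersections())
  expect_identical(ni_c$n_intersections, 3L)
  cls <- vapply(ni_c$fixed_points, function(f) f$classification, "")
  expect_identical(sum(cls %in% c("STABLE_NODE", "STABLE_FOCUS")), 2L)
  expect_identical(sum(cls == "SADDLE"), 1L)
  ni_b <- cached("null_buffered",
                 nullcline_intersections(config = ion_config(bath = "K_BATH")))
  expect_identical(ni_b$n_intersections, 1L)
  expect_identical(ni_b$fixed_points[[1]]$n_unstable, 0L)
  # sampled curve points satisfy the zeroed-rate condition
  cv <- nullcline_curve(K_i_grid = seq(125, 131, by = 1), which_rate = "K")
  ok <- which(cv$converged)
  expect_gt(length(ok), 3)
  p0 <- ion_params()
  for (i in ok[1:3]) {
    # reconstruct the full state and check dK_i/dt = 0
    Cl_i <- p0$Cl_i0 + (cv$Na_i[i] - p0$Na_i0) + (cv$K_i[i] - p0$K_i0) -
      10 * conversion_gamma(p0) * p0$C_m / p0$V_i * (cv$V[i] - p0$V0)
    s <- c(V = cv$V[i], n = gating_steady_states(cv$V[i])$n_inf,
           K_i = cv$K_i[i], Cl_i = Cl_i)
    r <- ion_rhs(0, s, p0, ion_config())
    expect_lt(abs(r[["K_i"]]), 1e-8)
  }
})

test_that("the buffered model is excitable: a suprathreshold pulse triggers
           a minute-scale FES transient with full return, subthreshold does
           not", {
  ex <- buffered_excitability()
  ev <- ex$events
  expect_identical(ev$classification, "PHYSIOLOGICAL")
  expect_gt(ev$n_spikes, 5)
  # transient depolarisation of roughly a minute, then hyperpolarisation
  expect_gt(ev$fes_duration, 45e3)
  expect_lt(ev$fes_duration, 90e3)
  expect_lt(ev$hyperpolarization_min, -80)
  # subthreshold pulse: prompt return, no FES
  exs <- excitability_run(protocol = protocol_na_pulse(amplitude = 5),
                          t_end = 60e3)
  expect_true(is.na(exs$events$fes_entry))
  expect_identical(exs$events$classification, "PHYSIOLOGICAL")
})

test_that("fixtures are deterministic in the seed and cover all variants", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2"); d3 <- tempfile("fx3")
  f1 <- make_fixtures(seed = 7, dir = d1)
  f2 <- make_fixtures(seed = 7, dir = d2)
  expect_identical(length(f1), 17L)  # 16 variant fixed points + trajectory
  h <- function(fs) vapply(fs, function(f) digest_file(f), "")
  digest_file <- function(f) paste(tools::md5sum(f), collapse = "")
  expect_identical(unname(h(f1)), unname(h(f2)))
  f3 <- make_fixtures(seed = 8, dir = d3)
  expect_false(identical(unname(h(f1)), unname(h(f3))))
  # fixtures load and pass the residual invariant
  fx <- jsonlite::fromJSON(f1[1])
  expect_lt(fx$residual, 1e-8)
})

test_that("plot front-ends return ggplot objects", {
  tr <- simulate_model(t_end = 1e3, n_out = 50)
  expect_s3_class(autoplot(tr), "ggplot")
  br <- cached("bistable_default", bistable_range())
  expect_s3_class(autoplot(br$branch_up), "ggplot")
  expect_s3_class(glance(br$branch_up), "tbl_df")
  expect_s3_class(tidy(detect_events(tr)), "tbl_df")
})
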