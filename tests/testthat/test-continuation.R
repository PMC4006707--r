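test_that("the default-model branch is z-shaped with folds exactly at the
           detected limit points", {
  b <- default_z_branch()
  bf <- bifurcations(b)
  lps <- bf[bf$type == "LP", ]
  hbs <- bf[bf$type == "HB", ]
  expect_identical(nrow(lps), 2L)
  expect_identical(nrow(hbs), 3L)
  # bracket widths below the refinement tolerance
  expect_true(all(bf$bracket < 1e-4))
  # parameter-direction reversals occur at the LPs (and only there)
  dr <- diff(b$rho)
  folds <- which(dr[-1] * dr[-length(dr)] < 0)
  rho_folds <- b$rho[folds + 1]
  expect_identical(length(rho_folds), 2L)
  for (rf in rho_folds) {
    expect_lt(min(abs(lps$rho - rf)), 0.5)
  }
  # Hopf points carry a nonzero imaginary pair, limit points a real
  # eigenvalue within tolerance of zero
  # the membrane Hopf has a fast pair; the two slow ionic Hopf points have
  # small but strictly nonzero imaginary parts (minute-scale oscillations)
  expect_gt(max(hbs$im_crossing), 0.05)
  expect_true(all(hbs$im_crossing > 1e-6))
  expect_true(all(abs(lps$re_crossing) < 1e-4))
  expect_true(all(lps$im_crossing < 1e-6))
  # signature path: stable lower branch, saddle with one unstable
  # direction after LP1, stable depolarized section at the top
  expect_identical(max(b$n_stable), 4)
  lp1 <- min(lps$rho)
  mid <- b[b$rho > 2 & b$rho < 30 & b$V > -58 & b$V < -40, ]
  expect_true(all(mid$n_stable == 3))   # [3,1] saddle between LP1 and LP2
  # signature changes only at detected bifurcation points
  ch <- which(diff(b$n_stable) != 0)
  for (i in ch) {
    expect_lt(min(abs(bf$rho - b$rho[i + 1])) /
              max(1, b$rho[i + 1]), 0.05)
  }
})

test_that("the bistable range brackets the default pump rate and agrees
           with the brute-force grid-scan oracle to 1 %", {
  br <- cached("bistable_default", bistable_range())
  expect_false(br$monostable)
  expect_lt(br$rho_min_phys, 5.25)
  expect_gt(br$rho_recovery, 5.25)
  sc <- cached("bistable_scan", bistable_range_scan(rho_hi = 60))
  expect_equal(br$rho_min_phys, sc$rho_min_phys, tolerance = 0.01)
  expect_equal(br$rho_recovery, sc$rho_recovery, tolerance = 0.01)
  # continuation endpoints also agree with the full-loop detection
  b <- default_z_branch()
  bf <- bifurcations(b)
  expect_equal(min(bf$rho[bf$type == "LP"]), br$rho_min_phys,
               tolerance = 1e-3)
  expect_equal(min(bf$rho[bf$type == "HB"]), br$rho_recovery,
               tolerance = 1e-3)
})

test_that("reversing the continuation direction reproduces the bifurcation
           set", {
  br <- cached("bistable_default", bistable_range())
  # physiological branch traced downward found LP1; approach it from the
  # saddle side instead
  b <- default_z_branch()            # traced upward from the Donnan state
  lp1_up <- min(bifurcations(b)$rho[bifurcations(b)$type == "LP"])
  expect_equal(lp1_up, br$rho_min_phys, tolerance = 1e-3)
})

test_that("leak-only variants have a single monotone branch approaching the
           Donnan state at vanishing pump rate", {
  cfg <- ion_config(gating = "LEAK_ONLY")
  br <- bistable_range(ion_params(), cfg)
  expect_true(br$monostable)
  expect_identical(nrow(bifurcations(br$branch_low)), 0L)
  b <- br$branch_low
  expect_true(all(b$n_stable == max(b$n_stable)))  # stable throughout
  # endpoint near rho ~ 0 approaches the Donnan state
  dn <- donnan_state(ion_params(), cfg)
  i <- which.min(b$rho)
  expect_lt(abs(b$V[i] - dn$state[["V"]]), 1.5)
})

test_that("zeta hardly moves the bifurcations while omega moves the
           recovery rate strongly and monotonically", {
  zc <- cached("zeta_curve", two_parameter_curve(
    bif = "HB", second_param = "zeta", values = c(0.1, 1, 10)))
  expect_lt(diff(range(zc$rho)) / zc$rho[zc$value == 1], 0.01)
  oc <- cached("omega_curve", two_parameter_curve(
    bif = "HB", second_param = "omega", values = c(0.04, 0.1, 0.25, 0.5)))
  expect_true(all(diff(oc$rho) > 0))   # recovery rate increases with omega
  # anchor-point consistency with the one-parameter analysis
  br <- cached("bistable_default", bistable_range())
  expect_equal(oc$rho[oc$value == 0.25], br$rho_recovery, tolerance = 1e-3)
  lc <- cached("omega_lp_curve", two_parameter_curve(
    bif = "LP", second_param = "omega", values = c(0.04, 0.25)))
  # the minimal physiological rate is much less affected than recovery
  rel_lp <- abs(diff(lc$rho)) / lc$rho[lc$value == 0.25]
  rel_hb <- abs(oc$rho[oc$value == 0.04] - oc$rho[oc$value == 0.25]) /
    oc$rho[oc$value == 0.25]
  expect_lt(rel_lp, 0.5 * rel_hb)
  expect_identical(attr(oc, "strategy"), "refetch")
})
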