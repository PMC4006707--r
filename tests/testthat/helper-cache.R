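## Expensive shared computations, evaluated lazily once per test run.
options(testthat.progress.max_fails = 1000)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

default_z_branch <- function() {
  cached("z_branch", {
    dn <- donnan_state()
    trace_branch(p_range = c(-0.05, 450), start_fp = dn, direction = +1,
                 ds0 = 0.005, max_steps = 6000)
  })
}

default_variant_sweep <- function() {
  cached("variant_sweep", variant_sweep())
}

buffered_excitability <- function() {
  cached("excitability", excitability_run(t_end = 7.2e6))
}

fig1a_trajectory <- function() {
  cached("fig1a", simulate_model(
    protocol = protocol_na_pulse(amplitude = 150, t_on = 10e3,
                                 duration = 1e3),
    t_end = 500e3, n_out = 4000))
}

fig1b_trajectory <- function() {
  cached("fig1b", simulate_model(
    protocol = protocol_pump_off(t_on = 10e3, duration = 30e3),
    t_end = 500e3, n_out = 2000))
}

depolarized_fp <- function() {
  cached("depol_fp", {
    tr <- fig1a_trajectory()
    nm <- names(tr)[3:6]  # V n K_i Cl_i
    y <- as.numeric(tr[nrow(tr), nm]); names(y) <- nm
    find_fixed_point(guess = y)
  })
}
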