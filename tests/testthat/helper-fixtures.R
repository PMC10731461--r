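# Shared test fixtures: fast solver settings and reduced parameter sets.

fast_solver <- function(grid_dt = 2) {
  solver_options(rtol = 1e-6, atol = 1e-8, grid_dt = grid_dt)
}

# initial-model parameters with saturating, non-consumed nutrients:
# monod factors ~1, so growth is a clean exponential at rate mum - kd
saturating_params <- function(mum = 0.05, kd = 0.01) {
  params_initial(kd = kd, mum = mum,
                 KS = 0, KIS = 1e12, KA = 0, KIA = 1e12, KN = 0, KIN = 1e12,
                 muS = 0, muA = 0, muN = 0, muP = 0, check_bounds = FALSE)
}

saturated_state <- function(Xa = 0.5, V = 2) {
  process_state(V = V, Xa = Xa, S = 100, A = 100, N = 100, P = 0.25)
}

# a hand-built trajectory object for peak-extraction tests
fake_trajectory <- function(times, Xa) {
  states <- cbind(V = 2, Xa = Xa, Xd = 0, S = 1, F = 0, G = 0,
                  A = 1, N = 1, P = 1)
  structure(list(times = times, states = states,
                 events = data.frame(), design = NULL, params = NULL),
            class = "by2_trajectory")
}

# standard MS-medium batch design at the given inoculum/sucrose
ms_design <- function(X0 = 0.75, S0_mM = 88, duration = 144,
                      sampling = seq(0, duration, 24), V = 2) {
  experiment_design(
    label = sprintf("ms_X0_%g", X0),
    state0 = process_state(V = V, Xa = X0,
                           S = to_internal(S0_mM, "S"),
                           A = to_internal(21, "A"),
                           N = to_internal(39, "N"),
                           P = to_internal(2.7, "P")),
    duration = duration, sampling_times = sampling)
}
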