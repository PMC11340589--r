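# Shared fixtures: everything is generated in code, no stored data.

default_input <- feng_input()
canonical <- canonical_frame_schedule()
fine_grid <- seq(0, 25, by = 0.5 / 60)

# the worked example parameter set used across the kinetic tests
example_params <- kinetic_params(K1 = 0.05, k2 = 0.4, k3 = 0.08, vb = 0.05)

# constant (non-bolus) input for closed-form limits
constant_input <- function(level) {
  plasma_input(function(t) rep(level, length(t)), model = "constant")
}

# random-but-reproducible parameter draws over a depot-realistic envelope
random_params <- function(n, seed = 7L, vb_max = 0.2) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(K1 = runif(1, 0.005, 0.3),
                   k2 = runif(1, 0.05, 1.5),
                   k3 = runif(1, 0.005, 0.6),
                   vb = runif(1, 0, vb_max))
  })
}

# independent ODE oracle for the 2T system (deSolve, tight tolerance)
ode_oracle_ct <- function(params, input_fn, t_grid) {
  f <- function(t, y, parms) {
    cp <- input_fn$cp(t)
    list(c(params$K1 * cp - (params$k2 + params$k3) * y[1],
           params$k3 * y[1]))
  }
  o <- deSolve::lsoda(c(0, 0), t_grid, f, NULL, rtol = 1e-11, atol = 1e-13)
  params$vb * input_fn$cb(t_grid) +
    (1 - params$vb) * (o[, 2] + o[, 3])
}

# noiseless TAC via the package forward model
noiseless_tac <- function(params, input_fn = default_input,
                          schedule = canonical) {
  simulate_tac(params, input_fn, schedule, noise_level = 0)
}
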