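# Shared fixtures: short-trial protocol settings keep single tests fast
# while preserving the trial structure (trials still dwarf the membrane
# time constant, so summaries are taken at steady state).

short_trials <- list(trial_steps = 4000, trauma_trial_steps = 12000,
                     interval_steps = 1000)

default_net <- function(seed = 1, ...) {
  build_network(network_spec(seed = seed, ...))
}

full_pattern <- function(net, which = 1, trauma = 0) {
  if (which == 1) input_vector(net, V1 = 1, A1 = 1, S1 = 1, trauma = trauma)
  else input_vector(net, V2 = 1, A2 = 1, S2 = 1, trauma = trauma)
}

# discrete-time closed form of the scalar leaky unit under constant input:
# V_t = I + (V_0 - I) * (1 - dt/tau)^t  (the exact solution of the Euler
# recursion, used as the independent oracle for the integrator)
leak_closed_form <- function(t, I, V0 = 0, tau = 10, dt = 1) {
  I + (V0 - I) * (1 - dt / tau)^t
}
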