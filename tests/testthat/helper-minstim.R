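# shared fixtures: small, fast configurations used across test files

# a quiet (noise-free, fixed-amplitude) config for exactness tests
quiet_config <- function(...) {
  args <- utils::modifyList(list(n_sweeps_per_potential = 50, m_total = 1.6,
                                 cv_q = 0, noise_sd = 0, seed = 1),
                            list(...))
  do.call(simulation_config, args)
}

# detection params whose charge threshold is consistent with the simulated
# quantal scale (the printed 0.9 pC default presupposes compound responses)
sim_params <- function(cfg, ...) {
  detection_params(charge_failure_threshold = suggest_charge_threshold(cfg), ...)
}

# run one simulated experiment through detection at both potentials
detect_experiment <- function(cfg, params = sim_params(cfg)) {
  sim <- simulate_minstim_experiment(cfg)
  list(sim = sim,
       events_hyper = classify_failures(sim$hyper, params),
       events_depol = classify_failures(sim$depol, params),
       params = params)
}

# row-bind the two potentials' event tables the way the pipeline does
combined_events <- function(det) {
  minstim:::new_event_table(
    rbind(as.data.frame(det$events_hyper), as.data.frame(det$events_depol)),
    noise_sd = max(attr(det$events_hyper, "noise_sd"),
                   attr(det$events_depol, "noise_sd")))
}

# a bare single-trace sweep for direct measurement tests: a biexponential
# response of given amplitude riding on zero baseline
single_quantum_trace <- function(amplitude, tau_rise, tau_decay,
                                 sampling_rate = 5000, stim_time = 10,
                                 sweep_length = 60, onset = 1) {
  t_ms <- (seq_len(round(sweep_length * sampling_rate / 1000)) - 1) /
    sampling_rate * 1000
  amplitude * biexp_waveform(t_ms - stim_time - onset, tau_rise, tau_decay)
}
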