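# analytic integral of the unit-peak biexponential over [a, b) ms after
# onset, written out independently of the package helpers
analytic_biexp_integral <- function(a, b, tr, td) {
  tp <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-tp / td) - exp(-tp / tr)
  (td * (exp(-a / td) - exp(-b / td)) - tr * (exp(-a / tr) - exp(-b / tr))) / peak
}

test_that("noise estimation matches its definition", {
  mk <- function(data) sweep_set(data, 5000, stim_time = 10,
                                 holding_potential = -60)
  p <- detection_params()
  expect_equal(estimate_noise(mk(matrix(0, 5, 300)), p)$sd, 0)
  # the SD is offset-invariant
  expect_equal(estimate_noise(mk(matrix(7.5, 5, 300)), p)$sd, 0)
  set.seed(1)
  noisy <- mk(matrix(rnorm(500 * 300, sd = 2), 500, 300))
  expect_equal(estimate_noise(noisy, p)$sd, 2, tolerance = 0.05)
  # window must fit: stimulus too early leaves no room
  early <- sweep_set(matrix(0, 2, 300), 5000, stim_time = 2,
                     holding_potential = -60)
  expect_error(estimate_noise(early, p), "window")
})

test_that("charge measurement integrates the half-open window", {
  p <- detection_params()
  len <- 300; fs <- 5000; stim <- 10
  t_ms <- (seq_len(len) - 1) / fs * 1000
  expect_equal(measure_charge(numeric(len), p, fs, stim), 0)
  # constant 10 pA deviation across the full 35 ms window: 0.35 pC exactly
  step <- ifelse(t_ms >= stim + 5 & t_ms < stim + 40, 10, 0)
  expect_equal(measure_charge(step, p, fs, stim), 0.35)
  # magnitude convention: an inward deflection gives the same charge
  expect_equal(measure_charge(-step, p, fs, stim), 0.35)
  # a single slow quantum matches the closed-form biexponential integral
  tr <- 5; td <- 60
  quantum <- single_quantum_trace(4.4, tr, td, fs, stim)
  expected <- 4.4 * analytic_biexp_integral(4, 39, tr, td) / 1000  # 1 ms onset
  expect_equal(measure_charge(quantum, p, fs, stim), expected,
               tolerance = 0.02)
})

test_that("peak measurement subtracts templates and finds biexponential peaks", {
  p <- detection_params()
  fs <- 5000; stim <- 10; len <- 300
  t_ms <- (seq_len(len) - 1) / fs * 1000
  artifact <- ifelse(t_ms >= stim & t_ms < stim + 0.5, 100,
                     ifelse(t_ms >= stim + 0.5 & t_ms < stim + 1, -100, 0))
  # exact cancellation of the artifact by the average-failure template
  pk <- measure_peak(artifact, average_failure = artifact, params = p,
                     sampling_rate = fs, stim_time = stim, direction = -1)
  expect_equal(pk$amplitude, 0)
  # synthetic fast quantum: peak amplitude and latency at the analytic values
  tr <- 1; td <- 8
  q <- single_quantum_trace(-9.7, tr, td, fs, stim)
  pk <- measure_peak(q, params = p, sampling_rate = fs, stim_time = stim,
                     direction = -1)
  expect_equal(pk$amplitude, -9.7, tolerance = 0.02)
  t_peak <- 1 + log(td / tr) * tr * td / (td - tr)   # onset + biexp peak time
  expect_equal(pk$latency, t_peak, tolerance = 0.3)
  expect_error(measure_peak(q, params = p, sampling_rate = fs,
                            stim_time = stim, direction = -1,
                            search_window = c(5, 5)), "empty")
})

test_that("noise-only peaks stay within the extreme-value envelope", {
  set.seed(8)
  p <- detection_params()
  fs <- 5000; stim <- 10
  peaks <- replicate(1000, {
    measure_peak(rnorm(300, sd = 2), params = p, sampling_rate = fs,
                 stim_time = stim, direction = -1)$amplitude
  })
  expect_gt(mean(abs(peaks)), 0)            # extreme-value bias is real
  expect_gte(mean(abs(peaks) < 4 * 2), 0.97)
})

test_that("failure classification honours the boundary semantics", {
  fs <- 5000; stim <- 10; len <- 300
  t_ms <- (seq_len(len) - 1) / fs * 1000
  in_cw <- t_ms >= stim + 5 & t_ms < stim + 40
  p <- detection_params()  # printed 0.9 pC threshold
  # +40 mV: charge at 0.5 pC and exactly 0.9 pC are failures ("did not
  # exceed"); above the threshold is a success
  mk_depol <- function(pA) sweep_set(rbind(ifelse(in_cw, pA, 0)), fs, stim,
                                     holding_potential = 40)
  charge_of <- function(pA, params = p) classify_failures(mk_depol(pA), params,
                                                          noise = 1)
  expect_true(charge_of(0.5 / 0.035)$failure)           # ~0.5 pC
  expect_false(charge_of(1.2 / 0.035)$failure)
  # a charge exactly equal to the threshold "did not exceed" it: failure
  at_boundary <- measure_charge(mk_depol(20)$data[1, ], p, fs, stim)
  p_eq <- detection_params(charge_failure_threshold = at_boundary)
  expect_true(charge_of(20, p_eq)$failure)
  # -60 mV with noise SD 2: |peak| 3 pA fails, 5 pA succeeds, and a peak
  # exactly at twice the noise ("smaller than") is a success
  mk_hyper <- function(pA) sweep_set(rbind(ifelse(t_ms >= stim + 1, -pA, 0)),
                                     fs, stim, holding_potential = -60)
  expect_true(classify_failures(mk_hyper(3), p, noise = 2)$failure)
  expect_false(classify_failures(mk_hyper(5), p, noise = 2)$failure)
  expect_false(classify_failures(mk_hyper(4), p, noise = 2)$failure)
  # unknown holding potential is a classification error
  field <- sweep_set(matrix(0, 1, len), fs, stim, holding_potential = NA)
  expect_error(classify_failures(field, p, noise = 1), "holding potential")
})

test_that("classification of noiseless well-separated sweeps reproduces ground truth", {
  cfg <- quiet_config(n_sweeps_per_potential = 80, silent_fraction = 0.3,
                      seed = 21)
  sim <- simulate_minstim_experiment(cfg)
  p <- sim_params(cfg)
  # zero recorded noise makes the 2-sigma criterion degenerate; classify
  # against a nominal noise floor well below the quantal amplitudes
  ev_h <- classify_failures(sim$hyper, p, noise = 0.5)
  ev_d <- classify_failures(sim$depol, p, noise = 0.5)
  truth <- sim$truth$counts
  expect_identical(ev_h$failure, truth$failure[truth$potential == -60])
  expect_identical(ev_d$failure, truth$failure[truth$potential == 40])
})

test_that("classification is invariant to a constant baseline offset", {
  cfg <- simulation_config(n_sweeps_per_potential = 40, silent_fraction = 0.4,
                           seed = 5)
  sim <- simulate_minstim_experiment(cfg)
  p <- sim_params(cfg)
  shifted <- sim$hyper
  shifted$data <- shifted$data + 12.5
  a <- classify_failures(sim$hyper, p)
  b <- classify_failures(shifted, p)
  expect_identical(a$failure, b$failure)
  expect_equal(b$peak_amplitude, a$peak_amplitude)
  expect_equal(b$charge, a$charge)
  expect_equal(b$amplitude, a$amplitude)
})

test_that("raising thresholds never decreases the failure count", {
  cfg <- simulation_config(n_sweeps_per_potential = 120, silent_fraction = 0.3,
                           seed = 9)
  sim <- simulate_minstim_experiment(cfg)
  base_thr <- suggest_charge_threshold(cfg)
  n_fail_depol <- vapply(base_thr * c(0.5, 1, 1.5, 2), function(thr) {
    sum(classify_failures(sim$depol,
                          detection_params(charge_failure_threshold = thr))$failure)
  }, numeric(1))
  expect_true(all(diff(n_fail_depol) >= 0))
  n_fail_hyper <- vapply(c(1, 2, 3), function(mult) {
    sum(classify_failures(sim$hyper,
                          detection_params(noise_multiplier = mult))$failure)
  }, numeric(1))
  expect_true(all(diff(n_fail_hyper) >= 0))
})

test_that("QC excludes drifting and noisy experiments but not short ones", {
  p <- detection_params()
  # run-down: strongly decreasing release across the recording
  cfg <- simulation_config(n_sweeps_per_potential = 300, silent_fraction = 0.25,
                           drift_slope = -1, seed = 31)
  det <- detect_experiment(cfg)
  ev <- qc_experiment(combined_events(det), det$params)
  qc <- attr(ev, "qc")
  expect_identical(qc$status, "exclude")
  expect_true(any(grepl("trend", qc$reasons)))
  expect_true(all(ev$excluded))

  # high background noise (stationary experiment, so noise is the only reason)
  flat <- detect_experiment(simulation_config(n_sweeps_per_potential = 300,
                                              silent_fraction = 0.25,
                                              seed = 32))
  ev2 <- qc_experiment(flat$events_depol, flat$params, noise = 5)
  expect_identical(attr(ev2, "qc")$status, "exclude")
  expect_identical(attr(ev2, "qc")$reasons, "noise")

  # too few sweeps for trend testing: indeterminate, not pass
  small <- detect_experiment(simulation_config(n_sweeps_per_potential = 6,
                                               seed = 2))
  ev3 <- qc_experiment(small$events_hyper, small$params, noise = 1)
  expect_identical(attr(ev3, "qc")$status, "indeterminate")
})
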