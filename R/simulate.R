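#' Configuration for the minimal-stimulation sweep simulator
#'
#' Collects and validates the parameters of the generative model used by
#' [simulate_minstim_experiment()]. The model is the exact inverse of the
#' analysis model: per sweep, the number of released quanta is Poisson with
#' mean `m_total` at +40 mV and `m_total * (1 - silent_fraction)` at -60 mV
#' (silent synapses pass current only at the depolarized potential). Each
#' quantum contributes a unit-peak biexponential waveform scaled by the
#' quantal amplitude times a truncated-normal variability multiplier.
#'
#' @param n_sweeps_per_potential number of sweeps recorded at each holding
#'   potential. Default 40, the middle of the conventional 20-50-event
#'   acquisition range for minimal stimulation.
#' @param m_total mean quantal content across all (silent + functional)
#'   synapses; dimensionless, > 0. Default 1.6, which places the
#'   depolarized-potential failure fraction (`exp(-1.6)` = 20\%) inside the
#'   10-40\% acquisition target.
#' @param silent_fraction population fraction `s` of silent synapses, in
#'   `[0, 1)`. Default 0 (no silent synapses) so that the phenomenon under
#'   study is always an explicit choice.
#' @param q_nmda quantal amplitude of the slow (NMDA-receptor) component at
#'   +40 mV, pA > 0. Default 4.4.
#' @param q_ampa quantal amplitude magnitude of the fast (AMPA-receptor)
#'   component at -60 mV, pA > 0 (currents are stored inward-negative, so
#'   simulated -60 mV responses have amplitude `-q_ampa`). Default 9.7.
#' @param cv_q coefficient of variation of the quantal amplitude, >= 0.
#'   Default 0.3.
#' @param tau_rise_fast,tau_decay_fast fast-component kinetics, ms
#'   (default 1 / 8).
#' @param tau_rise_slow,tau_decay_slow slow-component kinetics, ms
#'   (default 5 / 60, so the slow component still carries ~89\% of its peak
#'   at the conventional 25 ms read time).
#' @param noise_sd Gaussian noise SD added per sample, pA. Default 2.
#' @param sampling_rate samples per second. Default 5000.
#' @param stim_time stimulus time, ms from sweep start. Default 10.
#' @param sweep_length sweep duration, ms; must exceed
#'   `stim_time + 40` so the charge window fits. Default 60.
#' @param artifact_amplitude amplitude of the 1-ms biphasic stimulus
#'   artifact, pA. Default 100.
#' @param onset_latency synaptic delay between stimulus and response onset,
#'   ms. Default 1.
#' @param drift_slope optional linear trend in release across the recording,
#'   for QC testing: sweep `i` of `n` uses mean quantal content scaled by
#'   `1 + drift_slope * ((i-1)/(n-1) - 1/2)` (clamped at 0), i.e.
#'   `drift_slope = -1` ramps release from 150\% down to 50\% of nominal.
#'   Default 0 (stationary).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `"simulation_config"` (a validated list).
#' @seealso [simulate_minstim_experiment()], [suggest_charge_threshold()]
#' @export
simulation_config <- function(n_sweeps_per_potential = 40,
                              m_total = 1.6,
                              silent_fraction = 0,
                              q_nmda = 4.4,
                              q_ampa = 9.7,
                              cv_q = 0.3,
                              tau_rise_fast = 1, tau_decay_fast = 8,
                              tau_rise_slow = 5, tau_decay_slow = 60,
                              noise_sd = 2,
                              sampling_rate = 5000,
                              stim_time = 10,
                              sweep_length = 60,
                              artifact_amplitude = 100,
                              onset_latency = 1,
                              drift_slope = 0,
                              seed = NULL) {
  cfg <- list(n_sweeps_per_potential = n_sweeps_per_potential,
              m_total = m_total, silent_fraction = silent_fraction,
              q_nmda = q_nmda, q_ampa = q_ampa, cv_q = cv_q,
              tau_rise_fast = tau_rise_fast, tau_decay_fast = tau_decay_fast,
              tau_rise_slow = tau_rise_slow, tau_decay_slow = tau_decay_slow,
              noise_sd = noise_sd, sampling_rate = sampling_rate,
              stim_time = stim_time, sweep_length = sweep_length,
              artifact_amplitude = artifact_amplitude,
              onset_latency = onset_latency,
              drift_slope = drift_slope, seed = seed)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid simulation config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$n_sweeps_per_potential) && cfg$n_sweeps_per_potential >= 1,
      "n_sweeps_per_potential must be >= 1")
  chk(cfg$m_total > 0, "m_total must be > 0")
  chk(cfg$silent_fraction >= 0 && cfg$silent_fraction < 1,
      "silent_fraction must lie in [0, 1)")
  chk(cfg$q_nmda > 0 && cfg$q_ampa > 0, "quantal amplitudes must be > 0")
  chk(cfg$cv_q >= 0, "cv_q must be >= 0")
  chk(all(c(cfg$tau_rise_fast, cfg$tau_decay_fast,
            cfg$tau_rise_slow, cfg$tau_decay_slow) > 0),
      "time constants must be > 0")
  chk(cfg$tau_rise_fast < cfg$tau_decay_fast && cfg$tau_rise_slow < cfg$tau_decay_slow,
      "rise time constants must be smaller than decay time constants")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  chk(cfg$stim_time > 0 && cfg$stim_time < cfg$sweep_length, "stim_time must lie within the sweep")
  chk(cfg$sweep_length > cfg$stim_time + 40,
      "sweep_length must exceed stim_time + 40 ms (the charge window must fit)")
  chk(cfg$onset_latency >= 0, "onset_latency must be >= 0")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Minimal-stimulation simulation config\n")
  cat(sprintf("  %d sweeps/potential, m_total = %.3g, silent fraction = %.3g\n",
              x$n_sweeps_per_potential, x$m_total, x$silent_fraction))
  cat(sprintf("  q (NMDA/AMPA) = %.3g / %.3g pA, CV = %.2g, noise SD = %.3g pA\n",
              x$q_nmda, x$q_ampa, x$cv_q, x$noise_sd))
  cat(sprintf("  %g kHz, stim at %g ms, sweep %g ms\n",
              x$sampling_rate / 1000, x$stim_time, x$sweep_length))
  invisible(x)
}

# truncated-normal quantal-amplitude multipliers: 1 + cv * eps with eps a
# standard normal truncated below -1/cv, keeping amplitudes sign-consistent
rquantal_mult <- function(n, cv) {
  if (n == 0) return(numeric(0))
  if (cv == 0) return(rep(1, n))
  lo <- pnorm(-1 / cv)
  1 + cv * qnorm(lo + runif(n) * (1 - lo))
}

simulate_potential <- function(cfg, potential) {
  n <- cfg$n_sweeps_per_potential
  hyper <- potential < 0
  m_eff <- cfg$m_total * (if (hyper) 1 - cfg$silent_fraction else 1)
  ramp <- if (n == 1) 1 else
    pmax(0, 1 + cfg$drift_slope * ((seq_len(n) - 1) / (n - 1) - 0.5))
  k <- rpois(n, m_eff * ramp)
  mult <- rquantal_mult(sum(k), cfg$cv_q)
  amp_sum <- numeric(n)
  if (sum(k) > 0) {
    sums <- rowsum(mult, rep(seq_len(n), k))
    amp_sum[as.integer(rownames(sums))] <- sums[, 1]
  }
  q <- if (hyper) -cfg$q_ampa else cfg$q_nmda
  tau_r <- if (hyper) cfg$tau_rise_fast else cfg$tau_rise_slow
  tau_d <- if (hyper) cfg$tau_decay_fast else cfg$tau_decay_slow

  n_samp <- round(cfg$sweep_length * cfg$sampling_rate / 1000)
  t_ms <- (seq_len(n_samp) - 1) / cfg$sampling_rate * 1000
  w <- biexp_waveform(t_ms - cfg$stim_time - cfg$onset_latency, tau_r, tau_d)
  data <- outer(q * amp_sum, w)
  # biphasic 1-ms stimulus artifact, identical on every sweep
  art <- numeric(n_samp)
  art[t_ms >= cfg$stim_time & t_ms < cfg$stim_time + 0.5] <- cfg$artifact_amplitude
  art[t_ms >= cfg$stim_time + 0.5 & t_ms < cfg$stim_time + 1] <- -cfg$artifact_amplitude
  data <- sweep(data, 2, art, "+")
  if (cfg$noise_sd > 0)
    data <- data + matrix(rnorm(n * n_samp, 0, cfg$noise_sd), n, n_samp)

  sweeps <- sweep_set(data,
                      sampling_rate = cfg$sampling_rate,
                      stim_time = cfg$stim_time,
                      holding_potential = potential,
                      units = "pA",
                      metadata = data.frame(sweep_index = seq_len(n),
                                            acq_order = seq_len(n),
                                            timestamp = (seq_len(n) - 1) * 5))
  list(sweeps = sweeps, k = k)
}

#' Simulate a minimal-stimulation experiment with known ground truth
#'
#' Generates one experiment: a sweep set recorded at -60 mV, a sweep set at
#' +40 mV, and the per-sweep ground truth. At +40 mV the per-sweep quantum
#' count is Poisson(`m_total`); at -60 mV it is
#' Poisson(`m_total * (1 - silent_fraction)`) because silent synapses do not
#' conduct there. Responses are inward (negative) at -60 mV and outward
#' (positive) at +40 mV; a biphasic stimulus artifact and per-sample Gaussian
#' noise are added. Identical config + seed gives bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `hyper` (the -60 mV [sweep_set()]), `depol`
#'   (the +40 mV sweep set) and `truth`, itself a list holding the per-sweep
#'   `counts` data frame (potential, sweep index, quantum count, failure
#'   flag), the expected failure rates `rf_hyper = exp(-m(1-s))` and
#'   `rf_depol = exp(-m)`, and the true `silent_fraction`, `q_nmda`,
#'   `q_ampa`.
#' @examples
#' sim <- simulate_minstim_experiment(
#'   simulation_config(n_sweeps_per_potential = 20, silent_fraction = 0.5,
#'                     seed = 1))
#' mean(sim$truth$counts$k[sim$truth$counts$potential == -60] == 0)
#' @export
simulate_minstim_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  hyper <- simulate_potential(config, -60)
  depol <- simulate_potential(config, 40)
  n <- config$n_sweeps_per_potential
  counts <- data.frame(
    potential = rep(c(-60, 40), each = n),
    sweep_index = rep(seq_len(n), 2),
    k = c(hyper$k, depol$k))
  counts$failure <- counts$k == 0
  truth <- list(
    counts = counts,
    rf_hyper = exp(-config$m_total * (1 - config$silent_fraction)),
    rf_depol = exp(-config$m_total),
    silent_fraction = config$silent_fraction,
    q_nmda = config$q_nmda,
    q_ampa = config$q_ampa)
  list(hyper = hyper$sweeps, depol = depol$sweeps, truth = truth)
}

#' Simulate an fEPSP time course with a potentiation step
#'
#' Produces time-stamped synthetic field sweeps for testing the plasticity
#' module: before `induction_time` the expected 20-80\% rising slope equals
#' `baseline_slope`; afterwards it equals
#' `baseline_slope * potentiation_factor`. The fEPSP is stylized as a linear
#' 3-ms fall to the negative peak followed by an exponential decay, so the
#' fitted rising slope is exactly proportional to the per-sweep amplitude and
#' the noiseless LTP identities hold exactly. Amplitude noise is
#' multiplicative with coefficient of variation `noise_cv`.
#'
#' @param baseline_slope expected pre-induction rising slope, mV/ms
#'   (negative-going fEPSP, so conventionally negative; the magnitude is
#'   used to scale the waveform).
#' @param potentiation_factor multiplicative slope change after induction,
#'   > 0.
#' @param induction_time induction time, min from the start of the
#'   recording.
#' @param duration total recording duration, min; must exceed
#'   `induction_time`.
#' @param interval time between sweeps, min, > 0.
#' @param noise_cv coefficient of variation of the multiplicative amplitude
#'   noise, >= 0.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param sampling_rate,stim_time,sweep_length acquisition layout of each
#'   field sweep (Hz, ms, ms).
#' @param rise_ms,decay_ms waveform shape: duration of the linear falling
#'   phase and decay time constant, ms.
#' @return a list with `sweeps` (a [sweep_set()] in mV, no holding
#'   potential), `times` (sweep times, min) and `induction_time`.
#' @export
simulate_fepsp_course <- function(baseline_slope = -0.15,
                                  potentiation_factor = 1.5,
                                  induction_time = 20,
                                  duration = 80,
                                  interval = 1,
                                  noise_cv = 0.1,
                                  seed = NULL,
                                  sampling_rate = 5000,
                                  stim_time = 5,
                                  sweep_length = 50,
                                  rise_ms = 3,
                                  decay_ms = 15) {
  if (interval <= 0) stop("invalid config: interval must be > 0")
  if (duration <= induction_time) stop("invalid config: duration must exceed induction_time")
  if (potentiation_factor <= 0) stop("invalid config: potentiation_factor must be > 0")
  if (noise_cv < 0) stop("invalid config: noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = interval)
  n <- length(times)
  amp0 <- abs(baseline_slope) * rise_ms       # peak magnitude giving the target slope
  factor <- ifelse(times >= induction_time, potentiation_factor, 1)
  mult <- if (noise_cv > 0) pmax(0, 1 + noise_cv * rnorm(n)) else rep(1, n)
  amp <- amp0 * factor * mult

  n_samp <- round(sweep_length * sampling_rate / 1000)
  t_ms <- (seq_len(n_samp) - 1) / sampling_rate * 1000
  rel <- t_ms - stim_time - 1                  # 1 ms onset latency
  w <- numeric(n_samp)
  rising <- rel >= 0 & rel < rise_ms
  w[rising] <- -rel[rising] / rise_ms
  after <- rel >= rise_ms
  w[after] <- -exp(-(rel[after] - rise_ms) / decay_ms)
  data <- outer(amp, w)

  sweeps <- sweep_set(data, sampling_rate = sampling_rate,
                      stim_time = stim_time, holding_potential = NA,
                      units = "mV",
                      metadata = data.frame(sweep_index = seq_len(n),
                                            acq_order = seq_len(n),
                                            timestamp = times * 60))
  list(sweeps = sweeps, times = times, induction_time = induction_time)
}
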