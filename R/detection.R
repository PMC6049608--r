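#' Detection parameters
#'
#' Constants governing baseline/noise estimation, charge and peak
#' measurement, failure classification, and experiment-level QC.
#'
#' Boundary semantics follow the wording of the conventions implemented: at
#' the depolarized potential a sweep is a failure when its charge does not
#' exceed the threshold (charge equal to the threshold is a failure); at the
#' hyperpolarized potential a sweep is a failure when its peak is smaller
#' than `noise_multiplier` times the signal noise (a peak exactly at the
#' threshold is a success).
#'
#' @param charge_failure_threshold charge threshold for failures at +40 mV,
#'   pC. Default 0.9, the conventional printed value; see
#'   [suggest_charge_threshold()] for simulated-scale analyses.
#' @param charge_window half-open charge-integration window, ms
#'   post-stimulus. Default `c(5, 40)`.
#' @param noise_window_length length of the noise window, ms. Default 3.
#' @param noise_window_gap gap between the end of the (pre-stimulus) noise
#'   window and the stimulus, ms. Default 1.
#' @param peak_search_window half-open peak-search window at the
#'   hyperpolarized potential, ms post-stimulus. Default `c(1, 10)`, which
#'   covers the fast-component peak under the default kinetics.
#' @param nmda_read_time amplitude read time for the slow component at
#'   +40 mV, ms post-stimulus. Default 25.
#' @param noise_multiplier failure threshold at -60 mV in units of the noise
#'   SD. Default 2.
#' @param peak_smooth_ms boxcar width used to smooth traces before peak and
#'   point-amplitude reads, ms (0 disables). Default 1. Raw single-sample
#'   extrema of band-limited noise carry a large extreme-value bias; a light
#'   boxcar restores a usable peak-to-noise criterion.
#' @param stim_blank_ms length of the stimulus-artifact region blanked
#'   (replaced by the baseline) before peak measurement, ms from the
#'   stimulus. Default 1, the artifact duration; blanking keeps the boxcar
#'   from smearing the artifact into the peak search window.
#' @param trend_alpha experiment-wise significance level of the drift
#'   (run-up/run-down) exclusion test. Default 0.05.
#' @param min_rf_trend_change practical-significance floor for the drift
#'   test on the failure indicator: minimum absolute fitted change in
#'   failure probability across the recording. Default 0.25.
#' @param min_amp_trend_change floor for the drift test on success
#'   amplitudes: minimum fitted relative amplitude change. Default 0.25.
#' @param max_noise_sd noise ceiling for exclusion, pA; experiments whose
#'   noise SD exceeds it are excluded. Default 3, matched to the simulator's
#'   2 pA noise scale (the convention gives no printed value).
#' @param max_template_iter maximum iterations of the average-failure
#'   template refinement at -60 mV. Default 5.
#' @return an object of class `"detection_params"`.
#' @export
detection_params <- function(charge_failure_threshold = 0.9,
                             charge_window = c(5, 40),
                             noise_window_length = 3,
                             noise_window_gap = 1,
                             peak_search_window = c(1, 10),
                             nmda_read_time = 25,
                             noise_multiplier = 2,
                             peak_smooth_ms = 1,
                             stim_blank_ms = 1,
                             trend_alpha = 0.05,
                             min_rf_trend_change = 0.25,
                             min_amp_trend_change = 0.25,
                             max_noise_sd = 3,
                             max_template_iter = 5) {
  p <- list(charge_failure_threshold = charge_failure_threshold,
            charge_window = charge_window,
            noise_window_length = noise_window_length,
            noise_window_gap = noise_window_gap,
            peak_search_window = peak_search_window,
            nmda_read_time = nmda_read_time,
            noise_multiplier = noise_multiplier,
            peak_smooth_ms = peak_smooth_ms,
            stim_blank_ms = stim_blank_ms,
            trend_alpha = trend_alpha,
            min_rf_trend_change = min_rf_trend_change,
            min_amp_trend_change = min_amp_trend_change,
            max_noise_sd = max_noise_sd,
            max_template_iter = max_template_iter)
  stopifnot(p$charge_failure_threshold > 0,
            length(p$charge_window) == 2, diff(p$charge_window) > 0,
            p$noise_window_length > 0, p$noise_window_gap >= 0,
            length(p$peak_search_window) == 2, diff(p$peak_search_window) > 0,
            p$nmda_read_time > 0, p$noise_multiplier > 0,
            p$peak_smooth_ms >= 0, p$stim_blank_ms >= 0,
            p$trend_alpha > 0, p$trend_alpha < 1,
            p$max_noise_sd > 0, p$max_template_iter >= 1)
  structure(p, class = "detection_params")
}

# half-open window [lo, hi) on a vector of sample times (ms)
window_index <- function(times, lo, hi) which(times >= lo & times < hi)

noise_window <- function(params, stim_time) {
  hi <- stim_time - params$noise_window_gap
  c(hi - params$noise_window_length, hi)
}

# centered boxcar; edges fall back to the raw samples (all analysis windows
# lie in the interior)
smooth_trace <- function(y, width) {
  if (width <= 1) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / width, width), sides = 2))
  na <- is.na(s)
  s[na] <- y[na]
  s
}

smooth_width <- function(params, sampling_rate) {
  w <- round(params$peak_smooth_ms * sampling_rate / 1000)
  if (w %% 2 == 0) w <- w + 1
  max(w, 1)
}

#' Estimate the signal noise of a sweep set
#'
#' The noise is defined as the SD of the signal in a short pre-stimulus
#' window (default 3 ms, ending 1 ms before the stimulus so the artifact
#' cannot contaminate it), averaged over all sweeps at the holding
#' potential.
#'
#' @param sweeps a [sweep_set()].
#' @param params a [detection_params()].
#' @return an object of class `"noise_estimate"`: list with `sd` (pA),
#'   `n_sweeps` and the `window` used (ms from sweep start).
#' @export
estimate_noise <- function(sweeps, params = detection_params()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  win <- noise_window(params, sweeps$stim_time)
  idx <- window_index(sweep_times(sweeps), win[1], win[2])
  if (length(idx) < 2 || win[1] < 0)
    stop("noise window [", win[1], ", ", win[2], ") does not fit in the sweep")
  sds <- apply(sweeps$data[, idx, drop = FALSE], 1, sd)
  structure(list(sd = mean(sds), n_sweeps = n_sweeps(sweeps), window = win),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("Noise estimate: SD = %.3g (%d sweeps, window [%g, %g) ms)\n",
              x$sd, x$n_sweeps, x$window[1], x$window[2]))
  invisible(x)
}

#' Measure the post-stimulus charge of a single trace
#'
#' Baseline-subtracted integral of the current over the half-open charge
#' window (default 5-40 ms post-stimulus), returned as a magnitude in pC.
#' The baseline is the mean over the pre-stimulus noise window; the integral
#' is the Riemann sum of the samples in the half-open window times the
#' sample interval.
#'
#' @param trace numeric vector, one sweep, pA.
#' @param params a [detection_params()].
#' @param sampling_rate samples per second.
#' @param stim_time stimulus time, ms from sweep start.
#' @return charge magnitude in pC.
#' @export
measure_charge <- function(trace, params = detection_params(),
                           sampling_rate, stim_time) {
  times <- (seq_along(trace) - 1) / sampling_rate * 1000
  nw <- noise_window(params, stim_time)
  base <- mean(trace[window_index(times, nw[1], nw[2])])
  idx <- window_index(times, stim_time + params$charge_window[1],
                      stim_time + params$charge_window[2])
  if (length(idx) < 2) stop("charge window does not fit in the sweep")
  dt <- 1000 / sampling_rate
  abs(sum(trace[idx] - base) * dt) / 1000
}

#' Measure the peak of a single trace
#'
#' Optionally subtracts an average-failure template (removing the stimulus
#' artifact), subtracts the pre-stimulus baseline, lightly smooths the trace
#' (see [detection_params()]), and returns the extremum within the peak
#' search window in the direction of the holding potential (inward/negative
#' at -60 mV, outward/positive at +40 mV) together with its latency.
#'
#' @inheritParams measure_charge
#' @param average_failure optional template trace of the same length.
#' @param direction -1 for inward (hyperpolarized), +1 for outward
#'   (depolarized) responses.
#' @param search_window half-open window, ms post-stimulus; defaults to
#'   `params$peak_search_window`.
#' @return list with `amplitude` (signed, pA) and `latency` (ms
#'   post-stimulus).
#' @export
measure_peak <- function(trace, average_failure = NULL,
                         params = detection_params(),
                         sampling_rate, stim_time, direction = -1,
                         search_window = params$peak_search_window) {
  if (!is.null(average_failure)) {
    if (length(average_failure) != length(trace))
      stop("average_failure must have the same length as the trace")
    trace <- trace - average_failure
  }
  times <- (seq_along(trace) - 1) / sampling_rate * 1000
  nw <- noise_window(params, stim_time)
  base <- mean(trace[window_index(times, nw[1], nw[2])])
  blank <- window_index(times, stim_time, stim_time + params$stim_blank_ms)
  trace[blank] <- base
  y <- smooth_trace(trace, smooth_width(params, sampling_rate)) - base
  idx <- window_index(times, stim_time + search_window[1],
                      stim_time + search_window[2])
  if (length(idx) < 1) stop("empty peak search window")
  j <- if (direction < 0) which.min(y[idx]) else which.max(y[idx])
  list(amplitude = y[idx[j]], latency = times[idx[j]] - stim_time)
}

# vectorized peak extraction over the rows of a sweep matrix (already
# template-subtracted if needed); returns signed amplitudes and latencies
matrix_peaks <- function(data, params, sampling_rate, stim_time, direction,
                         search_window = params$peak_search_window) {
  times <- (seq_len(ncol(data)) - 1) / sampling_rate * 1000
  nw <- noise_window(params, stim_time)
  base <- rowMeans(data[, window_index(times, nw[1], nw[2]), drop = FALSE])
  blank <- window_index(times, stim_time, stim_time + params$stim_blank_ms)
  data[, blank] <- base
  w <- smooth_width(params, sampling_rate)
  sm <- t(apply(data, 1, smooth_trace, width = w)) - base
  idx <- window_index(times, stim_time + search_window[1],
                      stim_time + search_window[2])
  if (length(idx) < 1) stop("empty peak search window")
  sub <- sm[, idx, drop = FALSE]
  j <- apply(sub, 1, if (direction < 0) which.min else which.max)
  list(amplitude = sub[cbind(seq_len(nrow(sub)), j)],
       latency = times[idx][j] - stim_time,
       baseline = base)
}

#' Classify failures and successes in a sweep set
#'
#' Builds the event table for one sweep set. At the depolarized potential
#' (+40 mV) a sweep is a failure when its post-stimulus charge does not
#' exceed `charge_failure_threshold`; the stored amplitude is the
#' baseline-subtracted (smoothed) value read `nmda_read_time` ms after the
#' stimulus. At the hyperpolarized potential (-60 mV) a sweep is a failure
#' when the magnitude of its peak is smaller than
#' `noise_multiplier * noise$sd`; peaks are measured after subtraction of
#' the average-failure template, which removes the stimulus artifact.
#' Because the template itself depends on which sweeps are failures, the
#' classification is iterated to a fixed point: peaks are first measured on
#' the raw traces, the average failure is formed, peaks are re-measured on
#' template-subtracted traces and sweeps reclassified, up to
#' `max_template_iter` rounds.
#'
#' @param sweeps a [sweep_set()] with holding potential -60 or +40 mV.
#' @param params a [detection_params()].
#' @param noise a [noise_estimate()] for this sweep set (or a number, pA).
#' @return an event table (class `"event_table"`), one row per sweep, with
#'   the noise SD and parameters attached as attributes.
#' @export
classify_failures <- function(sweeps, params = detection_params(),
                              noise = estimate_noise(sweeps, params)) {
  stopifnot(inherits(sweeps, "sweep_set"))
  hp <- sweeps$holding_potential
  if (is.na(hp) || hp == 0)
    stop("classification error: unknown holding potential")
  noise_sd <- if (inherits(noise, "noise_estimate")) noise$sd else as.numeric(noise)
  data <- sweeps$data
  n <- nrow(data)
  times <- sweep_times(sweeps)
  dt <- 1000 / sweeps$sampling_rate
  nw <- noise_window(params, sweeps$stim_time)
  base_raw <- rowMeans(data[, window_index(times, nw[1], nw[2]), drop = FALSE])
  cw_idx <- window_index(times, sweeps$stim_time + params$charge_window[1],
                         sweeps$stim_time + params$charge_window[2])
  charge <- abs(rowSums(data[, cw_idx, drop = FALSE] - base_raw) * dt) / 1000

  if (hp > 0) {
    failure <- charge <= params$charge_failure_threshold
    pk <- matrix_peaks(data, params, sweeps$sampling_rate, sweeps$stim_time,
                       direction = 1,
                       search_window = c(params$peak_search_window[1],
                                         params$charge_window[2]))
    w <- smooth_width(params, sweeps$sampling_rate)
    sm <- t(apply(data, 1, smooth_trace, width = w))
    read_i <- which.min(abs(times - (sweeps$stim_time + params$nmda_read_time)))
    amplitude <- sm[, read_i] - base_raw
    peak_amp <- pk$amplitude
    peak_lat <- pk$latency
    baseline <- base_raw
  } else {
    failure <- rep(FALSE, n)
    template <- NULL
    for (it in seq_len(params$max_template_iter)) {
      d <- if (is.null(template)) data else sweep(data, 2, template, "-")
      pk <- matrix_peaks(d, params, sweeps$sampling_rate, sweeps$stim_time,
                         direction = -1)
      new_fail <- abs(pk$amplitude) < params$noise_multiplier * noise_sd
      converged <- identical(new_fail, failure) && it > 1
      failure <- new_fail
      if (converged) break
      template <- if (any(failure))
        colMeans(data[failure, , drop = FALSE]) else NULL
    }
    amplitude <- pk$amplitude
    peak_amp <- pk$amplitude
    peak_lat <- pk$latency
    baseline <- pk$baseline
  }

  new_event_table(data.frame(
    sweep_index = sweeps$metadata$sweep_index,
    holding_potential = hp,
    baseline = baseline,
    peak_amplitude = peak_amp,
    peak_latency = peak_lat,
    amplitude = amplitude,
    charge = charge,
    failure = failure,
    excluded = FALSE,
    exclude_reason = "",
    stringsAsFactors = FALSE),
    noise_sd = noise_sd, params = params)
}

trend_test <- function(y, x) {
  if (length(unique(y)) < 2 || length(x) < 3)
    return(list(p = NA_real_, change = 0))
  fit <- lm(y ~ x)
  co <- summary(fit)$coefficients
  if (nrow(co) < 2 || is.na(co[2, 4]))
    return(list(p = NA_real_, change = 0))
  list(p = co[2, 4], change = co[2, 1] * diff(range(x)))
}

#' Experiment-level quality control
#'
#' Flags an experiment for exclusion when (a) success amplitudes or the
#' failure indicator show a linear trend over acquisition order at either
#' holding potential (run-up/run-down), or (b) the background noise exceeds
#' `max_noise_sd`. The trend test is an ordinary least-squares slope t-test;
#' the per-test level is Bonferroni-corrected so the whole screen operates
#' at the experiment-wise level `trend_alpha`, and a trend is only acted on
#' when its fitted magnitude is also practically relevant (see
#' [detection_params()]). With fewer than 10 sweeps at any tested potential
#' the verdict is `"indeterminate"`, not a pass.
#'
#' @param events an event table from [classify_failures()], or several
#'   potentials' tables row-bound together (the `holding_potential` column
#'   distinguishes them).
#' @param params a [detection_params()].
#' @param noise noise SD in pA (a number or [noise_estimate()]); when two
#'   potentials were recorded pass the larger of the two estimates.
#' @return the event table with `excluded`/`exclude_reason` filled in
#'   (experiment-level verdicts mark every sweep) and an attribute `"qc"`:
#'   a list with `status` (`"pass"`, `"exclude"`, or `"indeterminate"`),
#'   `reasons`, and the table of trend `tests`.
#' @export
qc_experiment <- function(events, params = detection_params(),
                          noise = attr(events, "noise_sd")) {
  stopifnot(inherits(events, "event_table"))
  noise_sd <- if (inherits(noise, "noise_estimate")) noise$sd else as.numeric(noise)
  reasons <- character(0)
  indeterminate <- FALSE
  tests <- data.frame(potential = numeric(0), quantity = character(0),
                      p = numeric(0), change = numeric(0),
                      stringsAsFactors = FALSE)
  for (hp in sort(unique(events$holding_potential))) {
    sub <- events[events$holding_potential == hp & !events$excluded, ]
    if (nrow(sub) < 10) { indeterminate <- TRUE; next }
    succ <- sub[!sub$failure, ]
    if (nrow(succ) >= 3) {
      tr <- trend_test(succ$amplitude, succ$sweep_index)
      tests <- rbind(tests, data.frame(
        potential = hp, quantity = "amplitude", p = tr$p,
        change = tr$change / abs(mean(succ$amplitude))))
    }
    tr <- trend_test(as.numeric(sub$failure), sub$sweep_index)
    tests <- rbind(tests, data.frame(
      potential = hp, quantity = "failure_rate", p = tr$p, change = tr$change))
  }
  m <- sum(!is.na(tests$p))
  if (m > 0) {
    for (i in seq_len(nrow(tests))) {
      if (is.na(tests$p[i])) next
      floor_i <- if (tests$quantity[i] == "failure_rate")
        params$min_rf_trend_change else params$min_amp_trend_change
      if (tests$p[i] < params$trend_alpha / m && abs(tests$change[i]) >= floor_i)
        reasons <- c(reasons, sprintf("trend(%s, %+g mV)",
                                      tests$quantity[i], tests$potential[i]))
    }
  }
  if (is.finite(noise_sd) && noise_sd > params$max_noise_sd)
    reasons <- c(reasons, "noise")
  status <- if (length(reasons)) "exclude"
            else if (indeterminate) "indeterminate" else "pass"
  if (status == "exclude") {
    events$excluded <- TRUE
    events$exclude_reason <- paste(reasons, collapse = "; ")
  }
  attr(events, "qc") <- list(status = status, reasons = reasons,
                             tests = tests, noise_sd = noise_sd)
  events
}
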