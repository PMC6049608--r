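#' Parameters of the fEPSP rising-slope fit
#'
#' @param amplitude_fraction_low,amplitude_fraction_high bounds of the
#'   amplitude band on the rising (falling-voltage) phase used for the
#'   slope fit, as fractions of the peak amplitude; the conventional band is
#'   20-80\% (`0 < low < high < 1`).
#' @param baseline_window pre-stimulus baseline window as `c(start, end)`
#'   in ms before the stimulus (start > end >= 0). Default `c(5, 0.5)`.
#' @param search_window half-open window for the fEPSP negative-peak
#'   search, ms post-stimulus. The lower edge (default 2 ms) excludes the
#'   stimulus artifact and the fiber-volley region: the fitted deflection is
#'   the largest negative one whose latency exceeds it.
#' @param min_amplitude minimum peak magnitude counted as a response, mV.
#'   Default 0.05.
#' @return an object of class `"slope_fit_params"`.
#' @export
slope_fit_params <- function(amplitude_fraction_low = 0.2,
                             amplitude_fraction_high = 0.8,
                             baseline_window = c(5, 0.5),
                             search_window = c(2, 20),
                             min_amplitude = 0.05) {
  stopifnot(amplitude_fraction_low > 0,
            amplitude_fraction_low < amplitude_fraction_high,
            amplitude_fraction_high < 1,
            baseline_window[1] > baseline_window[2], baseline_window[2] >= 0,
            diff(search_window) > 0, min_amplitude > 0)
  structure(list(amplitude_fraction_low = amplitude_fraction_low,
                 amplitude_fraction_high = amplitude_fraction_high,
                 baseline_window = baseline_window,
                 search_window = search_window,
                 min_amplitude = min_amplitude),
            class = "slope_fit_params")
}

#' Fit the rising slope of a field EPSP
#'
#' Identifies the fEPSP negative peak after the stimulus (past the
#' artifact/fiber-volley exclusion latency), selects the samples on the
#' falling-voltage phase whose baseline-subtracted amplitude lies between
#' the 20\% and 80\% fractions of the peak amplitude, and returns the
#' least-squares line slope over those samples. Invariant to constant
#' voltage offsets.
#'
#' @param trace numeric vector, one field sweep, mV.
#' @param params a [slope_fit_params()].
#' @param sampling_rate samples per second.
#' @param stim_time stimulus time, ms from sweep start.
#' @return fitted slope, mV/ms (negative for a negative-going fEPSP).
#' @export
fit_fepsp_slope <- function(trace, params = slope_fit_params(),
                            sampling_rate, stim_time) {
  times <- (seq_along(trace) - 1) / sampling_rate * 1000
  b_idx <- window_index(times, stim_time - params$baseline_window[1],
                        stim_time - params$baseline_window[2])
  if (length(b_idx) < 1) stop("baseline window does not fit before the stimulus")
  y <- trace - mean(trace[b_idx])
  s_idx <- window_index(times, stim_time + params$search_window[1],
                        stim_time + params$search_window[2])
  if (length(s_idx) < 3) stop("peak search window does not fit in the sweep")
  pk <- s_idx[which.min(y[s_idx])]
  amp <- y[pk]
  if (amp > -params$min_amplitude)
    stop("no response: no negative peak exceeding ", params$min_amplitude, " mV")
  th_lo <- params$amplitude_fraction_low * amp    # 20% level (less negative)
  th_hi <- params$amplitude_fraction_high * amp   # 80% level (more negative)
  # walk backward from the peak: skip samples deeper than the 80% level,
  # then collect the contiguous run inside the band
  sel <- integer(0)
  i <- pk
  while (i > 1 && y[i] < th_hi) i <- i - 1
  while (i >= 1 && y[i] <= th_lo && y[i] >= th_hi) {
    sel <- c(i, sel)
    i <- i - 1
  }
  if (length(sel) < 3)
    stop("resolution error: fewer than 3 samples in the ",
         100 * params$amplitude_fraction_low, "-",
         100 * params$amplitude_fraction_high, "% band")
  unname(coef(lm(y[sel] ~ times[sel]))[2])
}

#' Normalize a slope time series to its pre-induction baseline
#'
#' Divides every slope by the mean over the pre-induction baseline sweeps
#' and expresses the series in percent, so the baseline mean is 100\% by
#' construction.
#'
#' @param slopes per-sweep fEPSP slopes (mV/ms).
#' @param times sweep times, min; same length as `slopes`.
#' @param induction_time induction time, min; at least 5 sweeps must
#'   precede it.
#' @return an object of class `"plasticity_course"`: data frame with
#'   columns `time`, `slope`, `norm` (\% of baseline) and attribute
#'   `induction_time`.
#' @export
normalize_course <- function(slopes, times, induction_time) {
  stopifnot(length(slopes) == length(times))
  base <- times < induction_time
  if (sum(base) < 5)
    stop("need at least 5 baseline sweeps before induction")
  ref <- mean(slopes[base])
  if (ref == 0) stop("baseline mean slope is zero")
  structure(data.frame(time = times, slope = slopes,
                       norm = 100 * slopes / ref),
            class = c("plasticity_course", "data.frame"),
            induction_time = induction_time)
}

#' Quantify potentiation in a post-induction window
#'
#' Mean normalized response in the half-open window, minus the 100\%
#' baseline: e.g. a flat post-induction course at 133\% gives 33\%
#' potentiation. Conventional windows are 2-3 h post-induction for
#' long-lasting LTP and 1-2 h for short-lasting LTP.
#'
#' @param course a [normalize_course()] result.
#' @param window `c(start, end)` in min after induction.
#' @return potentiation in percent of baseline.
#' @export
quantify_ltp <- function(course, window) {
  stopifnot(inherits(course, "plasticity_course"), length(window) == 2)
  t0 <- attr(course, "induction_time")
  if (window[1] < 0) stop("the quantification window must lie post-induction")
  sel <- course$time >= t0 + window[1] & course$time < t0 + window[2]
  if (!any(sel)) stop("no sweeps in the quantification window")
  mean(course$norm[sel]) - 100
}

#' Fit the input-output slope of basal transmission
#'
#' Basal synaptic transmission is expressed as a single slope fitted to the
#' input-output function of fEPSP slope versus fiber-volley amplitude.
#' The default fit is a least-squares line through the origin
#' (`sum(xy)/sum(x^2)`), since the input-output function passes through
#' (0, 0) physically; `through_origin = FALSE` fits an intercept instead.
#'
#' @param fiber_volley fiber-volley amplitudes (mV), >= 3 points.
#' @param fepsp_slope fEPSP slopes (mV/ms), same length.
#' @param through_origin constrain the line through the origin? Default
#'   `TRUE`.
#' @return fitted slope (dimensionless ratio of the two measures' units).
#' @export
fit_io_slope <- function(fiber_volley, fepsp_slope, through_origin = TRUE) {
  stopifnot(length(fiber_volley) == length(fepsp_slope))
  if (length(fiber_volley) < 3) stop("input-output fit needs at least 3 points")
  if (all(fiber_volley == 0)) stop("degenerate fit: all fiber volleys are zero")
  if (through_origin)
    sum(fiber_volley * fepsp_slope) / sum(fiber_volley^2)
  else
    unname(coef(lm(fepsp_slope ~ fiber_volley))[2])
}

#' Normalize input-output slopes to the wild-type population mean
#'
#' Divides every experiment's fitted slope by the mean over the wild-type
#' experiments within the same recording condition, so the wild-type group
#' mean is 1.00 exactly, independently in each condition.
#'
#' @param slopes per-experiment fitted input-output slopes.
#' @param genotype genotype labels, same length.
#' @param condition recording-condition labels (optional; a single
#'   condition when `NULL`).
#' @param wildtype the genotype label of the reference group. Default
#'   `"WT"`.
#' @return numeric vector of normalized slopes.
#' @export
normalize_io <- function(slopes, genotype, condition = NULL,
                         wildtype = "WT") {
  stopifnot(length(slopes) == length(genotype))
  if (is.null(condition)) condition <- rep("all", length(slopes))
  out <- numeric(length(slopes))
  for (cond in unique(condition)) {
    in_cond <- condition == cond
    wt <- in_cond & genotype == wildtype
    if (!any(wt))
      stop("no wild-type experiment in condition '", cond, "'")
    out[in_cond] <- slopes[in_cond] / mean(slopes[wt])
  }
  out
}

#' Fit slopes for every sweep of a field recording and normalize
#'
#' Convenience wrapper joining [fit_fepsp_slope()] and
#' [normalize_course()] for the output of [simulate_fepsp_course()] or a
#' field [sweep_set()] with per-sweep timestamps.
#'
#' @param sweeps a field [sweep_set()] (mV).
#' @param times sweep times, min.
#' @param induction_time induction time, min.
#' @param params a [slope_fit_params()].
#' @return a [normalize_course()] result.
#' @export
fepsp_course <- function(sweeps, times, induction_time,
                         params = slope_fit_params()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  slopes <- apply(sweeps$data, 1, fit_fepsp_slope, params = params,
                  sampling_rate = sweeps$sampling_rate,
                  stim_time = sweeps$stim_time)
  normalize_course(slopes, times, induction_time)
}
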