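#' Failure-rate estimate with exact binomial confidence bounds
#'
#' The failure rate is the fraction of non-excluded sweeps classified as
#' failures; its confidence interval is the exact (Clopper-Pearson)
#' binomial interval.
#'
#' @param events an event table from [classify_failures()].
#' @param conf_level confidence level of the interval. Default 0.95.
#' @return an object of class `"failure_rate_estimate"`: list with `rf`,
#'   `n_events`, `n_failures`, `conf_level`, `ci` (length-2 vector).
#' @export
estimate_failure_rate <- function(events, conf_level = 0.95) {
  stopifnot(inherits(events, "event_table"))
  kept <- events[!events$excluded, ]
  if (nrow(kept) < 1)
    stop("estimation error: all sweeps are excluded")
  n <- nrow(kept)
  k <- sum(kept$failure)
  ci <- as.numeric(binom.test(k, n, conf.level = conf_level)$conf.int)
  structure(list(rf = k / n, n_events = n, n_failures = k,
                 conf_level = conf_level, ci = ci),
            class = "failure_rate_estimate")
}

#' @export
print.failure_rate_estimate <- function(x, ...) {
  cat(sprintf("rf = %.3f (%d/%d failures, %g%% CI [%.3f, %.3f])\n",
              x$rf, x$n_failures, x$n_events, 100 * x$conf_level,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Mean quantal content from a failure rate
#'
#' Under the Poisson release model the failure rate is
#' \eqn{r_f = P(0) = e^{-m}}, so \eqn{m = -\ln r_f}.
#'
#' @param rf failure rate, in `(0, 1]`.
#' @return mean quantal content `m` (dimensionless).
#' @export
mean_quantal_content <- function(rf) {
  if (any(!is.finite(rf)) || any(rf > 1) || any(rf < 0))
    stop("domain error: failure rate must lie in (0, 1]")
  if (any(rf == 0))
    stop("rf = 0 leaves m unbounded; report a lower bound on m from the ",
         "exact binomial upper confidence bound on rf instead")
  -log(rf)
}

#' Poisson release probability
#'
#' \eqn{P(k) = m^k e^{-m} / k!}, the probability that `k` quanta are
#' released on a trial with mean quantal content `m`.
#'
#' @param k number of quanta, non-negative integer (vectorized).
#' @param m mean quantal content, > 0.
#' @return probability.
#' @export
poisson_pmf <- function(k, m) {
  if (any(k < 0) || any(k != round(k)))
    stop("domain error: k must be a non-negative integer")
  if (any(m <= 0)) stop("domain error: m must be > 0")
  exp(k * log(m) - m - lgamma(k + 1))
}

#' Silent-synapse fraction from failure rates at the two potentials
#'
#' Silent synapses conduct at +40 mV but not at -60 mV, so the mean quantal
#' content at -60 mV counts only the functional synapses:
#' \eqn{m_{-60} = m_{+40}(1-s)}. Hence
#' \deqn{s = 1 - \frac{\ln r_{f,-60}}{\ln r_{f,+40}}.}
#' Sampling noise can make the estimate negative
#' (\eqn{r_{f,-60} < r_{f,+40}}); negative values are returned as-is with a
#' `"sampling_noise_flag"` attribute rather than clipped.
#'
#' @param rf_hyper failure rate at -60 mV, in `(0, 1]`.
#' @param rf_depol failure rate at +40 mV, in `(0, 1)`.
#' @return estimated silent fraction (<= 1; vectorized), with attribute
#'   `"sampling_noise_flag"` marking negative estimates.
#' @examples
#' silent_fraction_estimate(0.363, 0.127)  # ~0.51
#' @export
silent_fraction_estimate <- function(rf_hyper, rf_depol) {
  if (any(rf_hyper <= 0) || any(rf_hyper > 1))
    stop("domain error: rf_hyper must lie in (0, 1]")
  if (any(rf_depol <= 0) || any(rf_depol >= 1))
    stop("domain error: rf_depol must lie in (0, 1) (rf = 1 gives m = 0, ",
         "rf = 0 leaves m unbounded)")
  s <- 1 - log(rf_hyper) / log(rf_depol)
  structure(s, sampling_noise_flag = s < 0)
}

#' Synaptic potency: mean amplitude of successes
#'
#' The apparent synaptic potency is the average amplitude of all
#' non-excluded sweeps that qualified as successes, using the amplitude
#' convention already stored in the event table (template-subtracted peak at
#' -60 mV; 25-ms read at +40 mV).
#'
#' @param events an event table from [classify_failures()].
#' @return potency in pA (signed: negative at -60 mV).
#' @export
compute_potency <- function(events) {
  stopifnot(inherits(events, "event_table"))
  succ <- events[!events$excluded & !events$failure, ]
  if (nrow(succ) < 1) stop("estimation error: no successes")
  mean(succ$amplitude)
}

#' Per-experiment quantal summary
#'
#' Combines the event tables of the two holding potentials into the
#' experiment-level payload: failure rates with exact binomial intervals,
#' mean quantal contents, the silent-fraction estimate, and potencies.
#'
#' @param events_hyper event table at -60 mV.
#' @param events_depol event table at +40 mV.
#' @param conf_level confidence level for the failure-rate intervals.
#' @return an object of class `"quantal_summary"`.
#' @export
quantal_summary <- function(events_hyper, events_depol, conf_level = 0.95) {
  rf_h <- estimate_failure_rate(events_hyper, conf_level)
  rf_d <- estimate_failure_rate(events_depol, conf_level)
  m_h <- if (rf_h$rf > 0) mean_quantal_content(rf_h$rf) else NA_real_
  m_d <- if (rf_d$rf > 0) mean_quantal_content(rf_d$rf) else NA_real_
  s <- if (rf_h$rf > 0 && rf_d$rf > 0 && rf_d$rf < 1)
    silent_fraction_estimate(rf_h$rf, rf_d$rf) else NA_real_
  pot_h <- tryCatch(compute_potency(events_hyper), error = function(e) NA_real_)
  pot_d <- tryCatch(compute_potency(events_depol), error = function(e) NA_real_)
  structure(list(rf_hyper = rf_h, rf_depol = rf_d,
                 m_hyper = m_h, m_depol = m_d,
                 silent_fraction_estimate = as.numeric(s),
                 silent_fraction_flagged = isTRUE(attr(s, "sampling_noise_flag")),
                 potency_hyper = pot_h, potency_depol = pot_d),
            class = "quantal_summary")
}

#' @export
print.quantal_summary <- function(x, ...) {
  cat("Quantal summary\n")
  cat(sprintf("  rf: %.3f (-60 mV), %.3f (+40 mV); m: %.3f / %.3f\n",
              x$rf_hyper$rf, x$rf_depol$rf, x$m_hyper, x$m_depol))
  cat(sprintf("  silent fraction: %.3f%s\n", x$silent_fraction_estimate,
              if (x$silent_fraction_flagged) " (negative: sampling noise)" else ""))
  cat(sprintf("  potency: %.2f pA (-60 mV), %.2f pA (+40 mV)\n",
              x$potency_hyper, x$potency_depol))
  invisible(x)
}

fit_through_origin <- function(x, y, conf_level) {
  q <- sum(x * y) / sum(x^2)
  res <- y - q * x
  n <- length(x)
  se <- sqrt(sum(res^2) / (n - 1) / sum(x^2))
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  list(q = q, se = se, ci = q + c(-1, 1) * tcrit * se,
       residual_sd = sqrt(sum(res^2) / max(n - 1, 1)), n = n)
}

#' Fit the mean quantal size from potency versus failure rate
#'
#' Across experiments, the synaptic potency is modeled as a function of the
#' failure rate and the single free parameter `q`, the mean quantal size.
#' Two formula variants are fitted (both are always computed and reported):
#' \describe{
#'   \item{`"paper"`}{\eqn{S = -\ln(r_f)\, q}: the conventional form, in
#'     which \eqn{-\ln(r_f) q = m q} is the mean response over all trials.}
#'   \item{`"corrected"`}{\eqn{S = -\ln(r_f)\, q / (1 - r_f)}: the mean
#'     over successes only, \eqn{q\,E[k \mid k \ge 1]}, which matches the
#'     definition of potency as the average success amplitude and is the
#'     variant to use for unbiased recovery of `q`.}
#' }
#' Each variant is linear in `q` given `rf`, so the fit is least squares
#' through the origin with a t-based confidence interval.
#'
#' @param rf failure rates, all in `(0, 1)`, one per experiment.
#' @param potency potencies (signed pA), same length.
#' @param variant which variant to report as primary.
#' @param conf_level confidence level. Default 0.95.
#' @return an object of class `"potency_fit"`: the primary `variant`, `q`,
#'   `se`, `ci`, `n`, and `fits`, a list with both variants' full results.
#' @export
fit_quantal_size <- function(rf, potency, variant = c("paper", "corrected"),
                             conf_level = 0.95) {
  variant <- match.arg(variant)
  if (length(rf) != length(potency)) stop("rf and potency lengths differ")
  keep <- complete.cases(rf, potency)
  rf <- rf[keep]; potency <- potency[keep]
  if (length(rf) < 3) stop("quantal-size fit needs at least 3 experiments")
  if (any(rf <= 0) || any(rf >= 1))
    stop("domain error: all failure rates must lie strictly in (0, 1)")
  x_paper <- -log(rf)
  fits <- list(paper = fit_through_origin(x_paper, potency, conf_level),
               corrected = fit_through_origin(x_paper / (1 - rf), potency,
                                              conf_level))
  structure(list(variant = variant, q = fits[[variant]]$q,
                 se = fits[[variant]]$se, ci = fits[[variant]]$ci,
                 conf_level = conf_level, n = length(rf), fits = fits),
            class = "potency_fit")
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf("Quantal-size fit (%d experiments)\n", x$n))
  for (v in names(x$fits)) {
    f <- x$fits[[v]]
    cat(sprintf("  %-9s q = %.3f pA (%g%% CI [%.3f, %.3f])%s\n",
                paste0(v, ":"), f$q, 100 * x$conf_level, f$ci[1], f$ci[2],
                if (v == x$variant) "  <- primary" else ""))
  }
  invisible(x)
}

#' AMPA/NMDA ratio from averaged EPSCs
#'
#' Averages the sweeps at each potential first and then measures on the
#' averaged trace: the AMPA-receptor component is the peak amplitude
#' magnitude of the averaged EPSC at -60 mV; the NMDA-receptor component is
#' the amplitude of the averaged EPSC read 25 ms after stimulation at
#' +40 mV. In mode `"minstim_all_sweeps"` (the minimal-stimulation
#' convention) the average runs across successes and failures alike; mode
#' `"compound"` labels averages of compound EPSC recordings, where the
#' computation is the same because no failure classification applies.
#'
#' @param sweeps_hyper [sweep_set()] at -60 mV.
#' @param sweeps_depol [sweep_set()] at +40 mV.
#' @param mode averaging mode label, `"minstim_all_sweeps"` or
#'   `"compound"`.
#' @param params a [detection_params()].
#' @return an object of class `"ampa_nmda_ratio"`: list with
#'   `ampa_component` (pA, magnitude), `nmda_component` (pA), `ratio`,
#'   `averaging_mode`.
#' @export
ampa_nmda_ratio <- function(sweeps_hyper, sweeps_depol,
                            mode = c("minstim_all_sweeps", "compound"),
                            params = detection_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(sweeps_hyper, "sweep_set"),
            inherits(sweeps_depol, "sweep_set"))
  avg_h <- colMeans(sweeps_hyper$data)
  avg_d <- colMeans(sweeps_depol$data)
  pk <- measure_peak(avg_h, params = params,
                     sampling_rate = sweeps_hyper$sampling_rate,
                     stim_time = sweeps_hyper$stim_time, direction = -1)
  ampa <- abs(pk$amplitude)
  times <- (seq_along(avg_d) - 1) / sweeps_depol$sampling_rate * 1000
  nw <- noise_window(params, sweeps_depol$stim_time)
  base <- mean(avg_d[window_index(times, nw[1], nw[2])])
  smd <- smooth_trace(avg_d, smooth_width(params, sweeps_depol$sampling_rate))
  read_i <- which.min(abs(times - (sweeps_depol$stim_time + params$nmda_read_time)))
  nmda <- smd[read_i] - base
  if (!is.finite(nmda) || nmda <= 0)
    stop("undefined ratio: averaged EPSC amplitude at the 25-ms read is not positive")
  structure(list(ampa_component = ampa, nmda_component = nmda,
                 ratio = ampa / nmda, averaging_mode = mode),
            class = "ampa_nmda_ratio")
}

#' @export
print.ampa_nmda_ratio <- function(x, ...) {
  cat(sprintf("AMPA/NMDA ratio = %.3f (AMPA %.2f pA, NMDA %.2f pA; %s)\n",
              x$ratio, x$ampa_component, x$nmda_component, x$averaging_mode))
  invisible(x)
}

#' Group summary in the reporting convention
#'
#' Parametric values are summarized as mean and standard error (with a
#' normal-theory confidence interval); nonparametric values as the median
#' with 25th and 75th percentiles plus minimum and maximum. Percentiles use
#' linear interpolation between order statistics ([stats::quantile()]
#' type 7). Inferential tests are deliberately out of scope.
#'
#' @param values numeric vector of per-experiment values, length >= 1.
#' @param parametric `TRUE` for mean +/- SE, `FALSE` for median and
#'   quartiles.
#' @param conf_level confidence level of the parametric interval.
#' @return a one-row data frame.
#' @export
summarize_groups <- function(values, parametric = TRUE, conf_level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("no values to summarize")
  n <- length(values)
  if (parametric) {
    se <- if (n > 1) sd(values) / sqrt(n) else NA_real_
    half <- if (n > 1) qt(1 - (1 - conf_level) / 2, n - 1) * se else NA_real_
    data.frame(n = n, mean = mean(values), se = se,
               ci_lo = mean(values) - half, ci_hi = mean(values) + half)
  } else {
    qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = n, median = qs[2], q25 = qs[1], q75 = qs[3],
               min = min(values), max = max(values))
  }
}
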