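# exact binomial bound by direct tail summation (independent of binom.test)
tail_inversion_upper <- function(k, n, conf = 0.95) {
  if (k == n) return(1)
  uniroot(function(p) sum(dbinom(0:k, n, p)) - (1 - conf) / 2,
          c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

fake_events <- function(failure, amplitude = ifelse(failure, 0, -10),
                        potential = -60, excluded = FALSE) {
  n <- length(failure)
  minstim:::new_event_table(data.frame(
    sweep_index = seq_len(n), holding_potential = potential,
    baseline = 0, peak_amplitude = amplitude, peak_latency = 3,
    amplitude = amplitude, charge = abs(amplitude) / 30,
    failure = failure, excluded = excluded, exclude_reason = "",
    stringsAsFactors = FALSE), noise_sd = 1)
}

test_that("failure rates come with exact binomial intervals", {
  ev <- fake_events(rep(c(TRUE, FALSE), c(5, 15)))
  est <- estimate_failure_rate(ev)
  expect_equal(est$rf, 0.25)
  expect_equal(est$n_failures, 5)
  # interval endpoints agree with direct tail-sum inversion
  expect_equal(est$ci[2], tail_inversion_upper(5, 20), tolerance = 1e-6)
  # zero failures: rf 0 with a one-sided exact upper bound
  est0 <- estimate_failure_rate(fake_events(rep(FALSE, 20)))
  expect_equal(est0$rf, 0)
  expect_equal(est0$ci[1], 0)
  expect_equal(est0$ci[2], 1 - (0.025)^(1 / 20), tolerance = 1e-6)
  # excluded sweeps do not count; all excluded is an error
  ev_x <- fake_events(rep(TRUE, 4), excluded = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(estimate_failure_rate(ev_x)$n_events, 2)
  expect_error(estimate_failure_rate(fake_events(TRUE, excluded = TRUE)),
               "excluded")
})

test_that("simulated failure rates track the Poisson closed form end to end", {
  cfg <- simulation_config(n_sweeps_per_potential = 10000, m_total = 2,
                           noise_sd = 0, seed = 12)
  det <- detect_experiment(cfg)
  est <- estimate_failure_rate(det$events_depol)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / 10000)
  expect_lt(abs(est$rf - exp(-2)), 3 * se)
  # rf -> m round trip lands near the simulator's m
  expect_equal(mean_quantal_content(est$rf), 2, tolerance = 3 * se / exp(-2))
})

test_that("mean quantal content inverts the failure rate", {
  expect_equal(mean_quantal_content(1), 0)
  expect_equal(mean_quantal_content(exp(-1)), 1)
  expect_equal(mean_quantal_content(0.127), 2.063568, tolerance = 1e-6)
  expect_error(mean_quantal_content(0), "unbounded")
  expect_error(mean_quantal_content(1.2), "domain")
  expect_error(mean_quantal_content(-0.1), "domain")
})

test_that("the Poisson pmf is exact and normalized", {
  expect_equal(poisson_pmf(0, 2), exp(-2))
  expect_equal(poisson_pmf(3, 1.5), 1.5^3 * exp(-1.5) / 6)
  expect_equal(sum(poisson_pmf(0:50, 2)), 1, tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 2), "domain")
  expect_error(poisson_pmf(2.5, 2), "domain")
  expect_error(poisson_pmf(2, 0), "domain")
})

test_that("the silent-fraction estimator matches its algebra", {
  # published knockout group means reproduce the ~51% figure
  expect_equal(as.numeric(silent_fraction_estimate(0.363, 0.127)), 0.509,
               tolerance = 1e-3)
  # equal failure rates mean no silent synapses
  for (r in c(0.1, 0.5, 0.9))
    expect_equal(as.numeric(silent_fraction_estimate(r, r)), 0)
  # exact inversion of the generative model
  m <- 1.7; s <- 0.4
  expect_equal(as.numeric(silent_fraction_estimate(exp(-m * (1 - s)), exp(-m))),
               s, tolerance = 1e-12)
  # negative estimates are flagged, not clipped
  est <- silent_fraction_estimate(0.1, 0.2)
  expect_lt(as.numeric(est), 0)
  expect_true(attr(est, "sampling_noise_flag"))
  expect_error(silent_fraction_estimate(0.5, 1), "domain")
  expect_error(silent_fraction_estimate(0, 0.5), "domain")
})

test_that("potency is the mean amplitude of successes", {
  ev <- fake_events(c(FALSE, FALSE, FALSE, TRUE),
                    amplitude = c(-8, -10, -12, 0))
  expect_equal(compute_potency(ev), -10)
  expect_equal(compute_potency(fake_events(FALSE, amplitude = -7.5)), -7.5)
  expect_error(compute_potency(fake_events(rep(TRUE, 3))), "no successes")
})

test_that("measured potency matches the conditional-Poisson expectation", {
  # with cv_q = 0 and no noise, potency ~ q * E[k | k >= 1] = q m / (1 - e^-m)
  m <- 0.7
  cfg <- simulation_config(n_sweeps_per_potential = 3000, m_total = m,
                           cv_q = 0, noise_sd = 0, seed = 17)
  det <- detect_experiment(cfg, sim_params(cfg))
  ev_h <- classify_failures(det$sim$hyper, det$params, noise = 0.5)
  oracle <- -9.7 * m / (1 - exp(-m))
  expect_equal(compute_potency(ev_h), oracle, tolerance = 0.03)
})

test_that("quantal-size fitting recovers constructed and perturbed points", {
  rf <- seq(0.1, 0.9, by = 0.1)
  s_paper <- -log(rf) * 5
  fit <- fit_quantal_size(rf, s_paper, variant = "paper")
  expect_equal(fit$q, 5, tolerance = 1e-12)
  expect_equal(fit$fits$paper$residual_sd, 0, tolerance = 1e-12)
  # the corrected variant fitted to the same points is systematically off
  expect_false(isTRUE(all.equal(fit$fits$corrected$q, 5, tolerance = 0.01)))
  expect_lt(fit$fits$corrected$q, 5)
  # points generated under the corrected model are recovered by it
  s_corr <- -log(rf) * 5 / (1 - rf)
  fit2 <- fit_quantal_size(rf, s_corr, variant = "corrected")
  expect_equal(fit2$q, 5, tolerance = 1e-12)
  expect_error(fit_quantal_size(c(0.1, 0.2), c(1, 2)), "3 experiments")
  expect_error(fit_quantal_size(c(0.1, 0.5, 1), c(1, 2, 3)), "domain")
})

test_that("AMPA/NMDA ratios follow the averaged-trace conventions", {
  fs <- 5000; stim <- 10; len <- 300
  t_ms <- (seq_len(len) - 1) / fs * 1000
  post <- t_ms >= stim + 0.5 & t_ms < stim + 45
  hyper <- sweep_set(rbind(ifelse(post, -30, 0)), fs, stim,
                     holding_potential = -60)
  depol <- sweep_set(rbind(ifelse(post, 15, 0)), fs, stim,
                     holding_potential = 40)
  r <- ampa_nmda_ratio(hyper, depol)
  expect_equal(r$ratio, 2, tolerance = 1e-10)
  expect_identical(r$averaging_mode, "minstim_all_sweeps")
  # symmetric construction: identical kinetics and read at the fast peak
  tr <- 1; td <- 8
  read_at <- 1 + log(td / tr) * tr * td / (td - tr)
  hyper2 <- sweep_set(rbind(single_quantum_trace(-9.7, tr, td, fs, stim)),
                      fs, stim, holding_potential = -60)
  depol2 <- sweep_set(rbind(single_quantum_trace(9.7, tr, td, fs, stim)),
                      fs, stim, holding_potential = 40)
  r2 <- ampa_nmda_ratio(hyper2, depol2,
                        params = detection_params(nmda_read_time = read_at))
  expect_equal(r2$ratio, 1, tolerance = 0.01)
  # negative-going average at +40 mV leaves the ratio undefined
  bad <- sweep_set(rbind(ifelse(post, -15, 0)), fs, stim,
                   holding_potential = 40)
  expect_error(ampa_nmda_ratio(hyper, bad), "undefined ratio")
})

test_that("more silent synapses lower the minimal-stimulation AMPA/NMDA ratio", {
  ratio_for <- function(s, seed) {
    cfg <- simulation_config(n_sweeps_per_potential = 200, silent_fraction = s,
                             seed = seed)
    sim <- simulate_minstim_experiment(cfg)
    ampa_nmda_ratio(sim$hyper, sim$depol)$ratio
  }
  wt <- vapply(1:5, function(i) ratio_for(0.1, 40 + i), numeric(1))
  ko <- vapply(1:5, function(i) ratio_for(0.5, 60 + i), numeric(1))
  expect_lt(mean(ko), mean(wt))
})

test_that("group summaries follow the reporting convention", {
  par <- summarize_groups(c(1, 2, 3), parametric = TRUE)
  expect_equal(par$mean, 2)
  expect_equal(par$se, 0.5773503, tolerance = 1e-6)
  nonpar <- summarize_groups(c(1, 2, 3, 100), parametric = FALSE)
  expect_equal(nonpar$median, 2.5)
  expect_equal(nonpar$q25, 1.75)    # type-7 linear interpolation
  expect_equal(nonpar$q75, 27.25)
  expect_equal(nonpar$min, 1)
  one <- summarize_groups(5, parametric = TRUE)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$se))
  expect_error(summarize_groups(numeric(0)), "no values")
})
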