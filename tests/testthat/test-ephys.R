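test_that("IPSC detection obeys the 3-sd / 10-ms rule on clean cases", {
  # injected 6-sd, 50 ms event well inside the window
  tr <- generate_ipsc_trace(events = data.frame(onset = 0.02, amplitude = 12,
                                                tau_decay = 0.05),
                            noise_sd = 2, post_s = 0.6, seed = 1)
  expect_true(detect_ipsc(tr)$present)
  # same amplitude but too brief: a fast-decaying event stays above
  # threshold for only ~6 ms
  brief <- generate_ipsc_trace(events = data.frame(onset = 0.02,
                                                   amplitude = 12,
                                                   tau_decay = 0.004),
                               noise_sd = 2, post_s = 0.6, seed = 2)
  expect_false(detect_ipsc(brief)$present)
  # events after the 500 ms window are ignored
  late <- generate_ipsc_trace(events = data.frame(onset = 0.55, amplitude = 50,
                                                  tau_decay = 0.05),
                              noise_sd = 2, post_s = 0.7, seed = 3)
  expect_false(detect_ipsc(late)$present)
  expect_error(detect_ipsc(trace_record(matrix(0, 11000, 2),
                                        stim_time = 1.05)), "extend")
})

test_that("IPSC detector error rates over seeded fixtures", {
  # false positives: pure noise, averaged over 5 trials
  fp <- vapply(1:1000, function(s) {
    tr <- generate_ipsc_trace(events = data.frame(onset = numeric(0),
                                                  amplitude = numeric(0),
                                                  tau_decay = numeric(0)),
                              noise_sd = 2, post_s = 0.55, seed = s)
    detect_ipsc(tr)$present
  }, logical(1))
  expect_lt(mean(fp), 0.01)
  # true positives: >= 5-sd-of-average events lasting >= 30 ms
  tp <- vapply(1:1000, function(s) {
    tr <- generate_ipsc_trace(events = data.frame(onset = 0.03, amplitude = 8,
                                                  tau_decay = 0.08),
                              noise_sd = 2, post_s = 0.55, seed = 10000 + s)
    detect_ipsc(tr)$present
  }, logical(1))
  expect_gt(mean(tp), 0.99)
})

test_that("phase metrics recover analytic charges", {
  # rectangular 10 pA, 100 ms pulse entirely within the early phase
  fs <- 1e4
  n <- as.integer(2.5 * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  x[t >= 1 & t < 1.1] <- 10
  tr <- trace_record(matrix(x, ncol = 1), stim_time = 1)
  m <- phase_metrics(tr)
  expect_equal(m$early_charge, 1.0, tolerance = 0.01)
  expect_equal(m$late_charge, 0, tolerance = 0.01)
  expect_equal(m$early_peak, 10)
  expect_equal(m$early_fraction, 1, tolerance = 0.01)
  # exponential IPSC, amplitude A and decay tau at stimulus onset:
  # early charge = A tau (1 - exp(-0.25/tau))
  A <- 20
  tau <- 0.05
  tr2 <- generate_ipsc_trace(events = data.frame(onset = 0, amplitude = A,
                                                 tau_decay = tau),
                             noise_sd = 0, seed = 4)
  m2 <- phase_metrics(tr2)
  expect_equal(m2$early_charge, A * tau * (1 - exp(-0.25 / tau)),
               tolerance = 0.01)
  expect_equal(m2$late_charge, A * tau * (exp(-0.25 / tau) - exp(-1.5 / tau)),
               tolerance = 0.01)
  expect_equal(m2$early_peak, A, tolerance = 0.01)
  # flat trace: everything zero, fraction undefined
  flat <- trace_record(matrix(0, n, 3), stim_time = 1)
  mf <- phase_metrics(flat)
  expect_equal(mf$early_peak + mf$late_peak +
                 mf$early_charge + mf$late_charge, 0)
  expect_true(is.na(mf$early_fraction))
})

test_that("early and late charges sum to the full-window integral", {
  tr <- generate_ipsc_trace(events = data.frame(onset = c(0.01, 0.4),
                                                amplitude = c(15, 6),
                                                tau_decay = c(0.04, 0.3)),
                            noise_sd = 1.5, seed = 5)
  m <- phase_metrics(tr)
  t <- (seq_len(nrow(tr$samples)) - 1) / tr$sample_rate
  avg <- rowMeans(tr$samples)
  base <- mean(avg[t >= tr$stim_time - 1 & t < tr$stim_time])
  full <- t >= tr$stim_time & t <= tr$stim_time + 1.5
  total <- pracma::trapz(t[full], (avg - base)[full])
  expect_equal(m$early_charge + m$late_charge, total, tolerance = 1e-8)
})

test_that("the effective-range rule matches hand-applied cases", {
  fi <- fi_curve_pair(1:5 * 100, c(10, 20, 40, 60, 80), c(10, 16, 30, 58, 80))
  er <- effective_range(fi)
  expect_identical(er$affected_steps, c(2L, 3L))
  expect_true(er$significant)
  expect_equal(er$lower_bound, 20)
  expect_equal(er$upper_bound, 40)
  # a single isolated decrease is not significant
  fi1 <- fi_curve_pair(1:5 * 100, c(10, 20, 40, 60, 80), c(10, 20, 30, 58, 80))
  er1 <- effective_range(fi1)
  expect_identical(er1$affected_steps, 3L)
  expect_false(er1$significant)
  expect_true(is.na(er1$lower_bound))
  # no change at all
  fi2 <- fi_curve_pair(1:3 * 100, c(10, 20, 30), c(10, 20, 30))
  expect_false(effective_range(fi2)$significant)
  # exactly 10% is not "greater than 10%"
  fi3 <- fi_curve_pair(1:3 * 100, c(20, 40, 60), c(18, 36, 54))
  expect_false(effective_range(fi3)$significant)
  expect_error(effective_range(fi_curve_pair(1:3, c(0, 0, 0), c(0, 0, 0))),
               "undefined")
})

test_that("the effective range ignores sub-threshold steps outside the run", {
  base <- fi_curve_pair(1:4 * 100, c(20, 40, 60, 80), c(16, 30, 60, 80))
  er0 <- effective_range(base)
  # append steps with <10% decreases on both sides of the affected run
  ext <- fi_curve_pair(c(50, 1:4 * 100, 500, 600),
                       c(10, 20, 40, 60, 80, 90, 100),
                       c(9.5, 16, 30, 60, 80, 85, 100))
  er1 <- effective_range(ext)
  expect_equal(er1$lower_bound, er0$lower_bound)
  expect_equal(er1$upper_bound, er0$upper_bound)
})

test_that("effective-range recovery from the FI fixture generator", {
  # true affected off-rates span ~10-43 Hz with a 15% decrease, echoing the
  # tufted-cell range
  fi <- generate_fixture("fi_pair",
                         params = list(current_steps = seq(40, 400, by = 40),
                                       max_rate = 86, affected_steps = 2:5,
                                       decrease_frac = 0.15, noise_sd = 0.4),
                         seed = 6)
  truth <- attr(fi, "truth")
  er <- effective_range(fi)
  expect_true(er$significant)
  step_hz <- 86 / 10
  expect_lte(abs(er$lower_bound - truth$lower_bound), step_hz)
  expect_lte(abs(er$upper_bound - truth$upper_bound), step_hz)
})

test_that("fixture generators are deterministic and truthful", {
  a <- generate_ipsc_trace(seed = 7)
  b <- generate_ipsc_trace(seed = 7)
  expect_identical(a, b)
  fa <- generate_fi_pair(seed = 8)
  fb <- generate_fi_pair(seed = 8)
  expect_identical(fa, fb)
  none <- generate_ipsc_trace(events = data.frame(onset = numeric(0),
                                                  amplitude = numeric(0),
                                                  tau_decay = numeric(0)),
                              post_s = 0.6, seed = 9)
  expect_false(detect_ipsc(none)$present)
})

test_that("trace records round-trip through their delimited format", {
  tr <- generate_ipsc_trace(noise_sd = 1, n_trials = 3, post_s = 0.6,
                            seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_record(tr, path)
  back <- read_trace_record(path)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_equal(back$stim_time, tr$stim_time)
  expect_equal(unname(back$samples), unname(tr$samples), tolerance = 1e-6)
  expect_equal(detect_ipsc(back)$present, detect_ipsc(tr)$present)
})
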