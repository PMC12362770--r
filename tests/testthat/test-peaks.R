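test_that("a polynomial signal is its own baseline", {
  t <- seq(0, 60, by = 0.01)
  tr <- tibble::tibble(time_s = t, signal_au = 5 + 0.3 * t - 0.002 * t^2)
  bl <- estimate_baseline(tr, degree = 2)
  expect_lt(max(abs(bl - tr$signal_au)), 1e-8)

  tr0 <- tibble::tibble(time_s = t, signal_au = 0)
  expect_true(all(abs(estimate_baseline(tr0)) < 1e-12))
})

test_that("baseline recovery under sparse positive pulses", {
  tr <- make_pulse_trace(times = seq(3, 57, by = 6), amps = rep(10, 10),
                         sigma = 0.05, baseline_fun = function(t) rep(5, length(t)))
  bl <- estimate_baseline(tr, degree = 3)
  expect_true(all(abs(bl - 5) / 5 < 0.02))
})

test_that("baseline argument validation", {
  tr <- make_pulse_trace(times = 1, amps = 1, sigma = 0.05, duration = 2)
  expect_error(estimate_baseline(tr, degree = -1), "degree")
  expect_error(estimate_baseline(tr, degree = nrow(tr)), "smaller")
  expect_error(estimate_baseline(tr, max_iter = 0), "max_iter")
})

test_that("the relative amplitude rule rejects sub-threshold maxima", {
  # apex amplitudes 100, 50, 9: the 9 sits below 10% of the maximum
  tr <- make_pulse_trace(times = c(10, 30, 50), amps = c(100, 50, 9),
                         sigma = 0.1, duration = 60)
  pk <- detect_peaks(tr, baseline = rep(0, nrow(tr)))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$amplitude_au, c(100, 50), tolerance = 1e-3)

  # raising the threshold above 50% leaves only the tallest
  pk2 <- detect_peaks(tr, baseline = rep(0, nrow(tr)), rel_threshold = 0.6)
  expect_equal(nrow(pk2), 1)
})

test_that("a single pulse is found at its true position", {
  tr <- make_pulse_trace(times = 20, amps = 8, sigma = 0.05, duration = 40)
  pk <- detect_peaks(tr, baseline = rep(0, nrow(tr)))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$apex_time_s - 20), 1 / 200 + 1e-12)
  expect_lt(pk$left_time_s, 20)
  expect_gt(pk$right_time_s, 20)
})

test_that("well-separated events are all found with no spurious extras", {
  times <- seq(1, 59, by = 2)
  set.seed(42)
  amps <- 6 * exp(rnorm(30, 0, 0.25))
  tr <- make_pulse_trace(times, amps, sigma = 0.05, duration = 60,
                         sample_rate = 1000,
                         baseline_fun = function(t) 2 + 0.01 * t,
                         noise_sd = 0.05, seed = 7)
  pk <- detect_peaks(tr)
  expect_gte(nrow(pk), 29)
  matched <- vapply(pk$apex_time_s,
                    function(tt) min(abs(times - tt)) < 0.02, logical(1))
  expect_true(all(matched)) # zero spurious detections
})

test_that("empty and all-noise traces give empty peak tables", {
  expect_equal(nrow(detect_peaks(tibble::tibble(time_s = numeric(0),
                                                signal_au = numeric(0)))), 0)
  t <- seq(0, 10, by = 0.005)
  tr <- tibble::tibble(time_s = t, signal_au = -abs(sin(t)))
  pk <- detect_peaks(tr, baseline = rep(0, length(t)))
  expect_equal(nrow(pk), 0)
})

test_that("trapezoidal area is exact for a triangular pulse", {
  t <- seq(0, 2, by = 0.01)
  y <- pmax(0, 10 * (1 - abs(t - 1) / 0.5))
  tr <- tibble::tibble(time_s = t, signal_au = y)
  a <- peak_area(tr, rep(0, length(t)),
                 tibble::tibble(left_time_s = 0.5, right_time_s = 1.5))
  expect_equal(a, 5.0)
})

test_that("Gaussian pulse area matches the analytic integral", {
  sigma <- 0.02
  t <- seq(0, 1, by = 1e-4)
  tr <- tibble::tibble(time_s = t,
                       signal_au = 20 * exp(-(t - 0.5)^2 / (2 * sigma^2)))
  a <- peak_area(tr, rep(0, length(t)),
                 tibble::tibble(left_time_s = 0.5 - 4 * sigma,
                                right_time_s = 0.5 + 4 * sigma))
  expect_equal(a, 20 * sigma * sqrt(2 * pi), tolerance = 0.005)
})

test_that("zero-height peaks integrate to zero and boundaries are checked", {
  t <- seq(0, 1, by = 0.01)
  tr <- tibble::tibble(time_s = t, signal_au = rep(0, length(t)))
  a <- peak_area(tr, rep(0, length(t)),
                 tibble::tibble(left_time_s = 0.2, right_time_s = 0.8))
  expect_equal(a, 0)
  expect_error(peak_area(tr, rep(0, length(t)),
                         tibble::tibble(left_time_s = -1, right_time_s = 0.5)),
               "inside the trace")
})

test_that("scan validity enforces the 10-peaks-per-30-s rule", {
  mk <- function(n, t_max = 29) {
    tibble::tibble(apex_time_s = seq(1, t_max, length.out = n),
                   area_aus = rep(2, n))
  }
  expect_true(summarize_scan(mk(10), window = c(0, 30))$valid)
  expect_false(summarize_scan(mk(9), window = c(0, 30))$valid)

  # a 60-s scan needs both 30-s tiles populated
  lopsided <- tibble::tibble(apex_time_s = seq(1, 29, length.out = 20),
                             area_aus = rep(1, 20))
  expect_false(summarize_scan(lopsided, window = c(0, 60))$valid)
  both <- tibble::tibble(apex_time_s = c(seq(1, 29, length.out = 12),
                                         seq(31, 59, length.out = 12)),
                         area_aus = rep(1, 24))
  expect_true(summarize_scan(both, window = c(0, 60))$valid)
})

test_that("F1 is the arithmetic mean of peak areas and F_ratio uses F0", {
  pk <- tibble::tibble(apex_time_s = seq(1, 29, length.out = 12),
                       area_aus = rep(c(2, 4, 6), 4))
  sm <- summarize_scan(pk, window = c(0, 30), f0 = 2)
  expect_equal(sm$F1_aus, 4.0)
  expect_equal(sm$F_ratio, 2.0)
  expect_equal(sm$n_peaks, 12)

  none <- summarize_scan(pk[0, ], window = c(0, 30))
  expect_false(none$valid)
  expect_true(is.na(none$F1_aus))
})

test_that("raising the threshold never increases the retained peak count", {
  scan <- generate_scan(synth_spec(duration = 30, sample_rate = 500, seed = 11))
  tr <- trace_channel(scan$traces, "ch605_au")
  bl <- estimate_baseline(tr)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8),
                   function(th) nrow(detect_peaks(tr, bl, rel_threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("polynomial drift is absorbed by the baseline stage", {
  scan <- generate_scan(synth_spec(duration = 30, sample_rate = 500, seed = 23))
  tr <- trace_channel(scan$traces, "ch655_au")
  f1 <- function(trace) {
    pk <- detect_peaks(trace)
    summarize_scan(pk, c(0, 30))$F1_aus
  }
  base <- f1(tr)
  drift <- tr
  drift$signal_au <- drift$signal_au +
    4 + 0.3 * drift$time_s - 0.02 * drift$time_s^2 +
    3e-4 * drift$time_s^3
  expect_lt(abs(f1(drift) - base) / base, 0.02)
})

test_that("analysis is equivariant under positive rescaling", {
  scan <- generate_scan(synth_spec(duration = 30, sample_rate = 500, seed = 31))
  tr <- trace_channel(scan$traces, "ch605_au")
  pk1 <- detect_peaks(tr)
  for (c_scale in c(3, 40)) {
    tr2 <- tr
    tr2$signal_au <- c_scale * tr2$signal_au
    pk2 <- detect_peaks(tr2)
    expect_equal(nrow(pk2), nrow(pk1))
    expect_equal(pk2$apex_index, pk1$apex_index)
    expect_equal(pk2$amplitude_au, c_scale * pk1$amplitude_au,
                 tolerance = 1e-9)
    expect_equal(pk2$area_aus, c_scale * pk1$area_aus, tolerance = 1e-9)
  }
})

test_that("end-to-end areas on noiseless scans match the generator truth", {
  sp <- synth_spec(duration = 60, sample_rate = 1000, noise_sd = 0,
                   contaminant_rate = 0, seed = 13,
                   baseline_coeffs = list(ch605_au = c(2, 0.01),
                                          ch655_au = c(2, 0.01)))
  scan <- generate_scan(sp)
  for (ch in c("ch605_au", "ch655_au")) {
    tr <- trace_channel(scan$traces, ch)
    pk <- detect_peaks(tr)
    truth <- scan$truth$events[scan$truth$events$channel == ch, ]
    # isolated events only: the analytic single-pulse integral is the oracle
    gap <- vapply(seq_len(nrow(truth)), function(i) {
      min(abs(truth$time_s[-i] - truth$time_s[i]))
    }, numeric(1))
    iso <- truth[gap > 0.5, ]
    err <- vapply(seq_len(nrow(iso)), function(i) {
      j <- which.min(abs(pk$apex_time_s - iso$time_s[i]))
      expect_lt(abs(pk$apex_time_s[j] - iso$time_s[i]), 0.01)
      abs(pk$area_aus[j] - iso$area_aus[i]) / iso$area_aus[i]
    }, numeric(1))
    # the estimated baseline's equilibrium sits a few millivolts low near
    # pulse-dense stretches, so the smallest pulses carry a slightly larger
    # relative error than the 1% typical of the bulk
    expect_gte(mean(err < 0.01), 0.9)
    expect_true(all(err < 0.03))
  }
})
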