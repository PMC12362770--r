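quiet_spec <- function(..., duration = 30, sample_rate = 200) {
  # small, fast spec used for structural checks
  synth_spec(duration = duration, sample_rate = sample_rate, ...)
}

test_that("spec validation catches inconsistent settings", {
  expect_error(synth_spec(sample_rate = 100, pulse_width_mean = 0.05),
               "8 samples")
  expect_error(synth_spec(bead_loss = 1.2), "bead_loss")
  expect_error(synth_spec(crosstalk = matrix(c(1, 1, 0, 1), 2)), "crosstalk")
  expect_error(synth_spec(amplitude_mean = c(1, 2)), "named")
  expect_error(synth_spec(noise_sd = -1), "noise_sd")
})

test_that("empty configuration yields a flat zero trace", {
  sp <- quiet_spec(event_rate = 0, noise_sd = 0, contaminant_rate = 0,
                   baseline_coeffs = list(ch605_au = 0, ch655_au = 0))
  scan <- generate_scan(sp)
  expect_true(all(scan$traces$ch605_au == 0))
  expect_true(all(scan$traces$ch655_au == 0))
  expect_equal(nrow(scan$truth$events), 0)
})

test_that("event counts follow the ~1 bead per second arrival rate", {
  # 30-s frames should carry ~30 transit pulses on average
  counts <- vapply(1:200, function(s) {
    sp <- quiet_spec(event_rate = 1, bead_loss = 0, contaminant_rate = 0,
                     noise_sd = 0, seed = s)
    sum(generate_scan(sp)$truth$events$channel == "ch655_au")
  }, numeric(1))
  se <- sqrt(30 / length(counts))
  expect_lt(abs(mean(counts) - 30), 3 * se)
})

test_that("bead loss thins the retained event count", {
  n_kept <- vapply(1:100, function(s) {
    sp <- quiet_spec(bead_loss = 0.2, contaminant_rate = 0, noise_sd = 0,
                     seed = s)
    ev <- generate_scan(sp)$truth$events
    sum(ev$kind == "bead" & ev$channel == "ch655_au")
  }, numeric(1))
  se <- sqrt(24 / length(n_kept))
  expect_lt(abs(mean(n_kept) - 0.8 * 30), 3 * se)
})

test_that("a lone noiseless pulse reproduces its amplitude at the apex", {
  found <- FALSE
  for (s in 1:50) {
    sp <- quiet_spec(event_rate = 1 / 30, bead_loss = 0, contaminant_rate = 0,
                     noise_sd = 0, height_cv = 0.3, seed = s,
                     baseline_coeffs = list(ch605_au = c(3, 0.05),
                                            ch655_au = c(3, 0.05)))
    scan <- generate_scan(sp)
    ev <- scan$truth$events[scan$truth$events$channel == "ch655_au", ]
    if (nrow(ev) != 1) next
    found <- TRUE
    corrected <- scan$traces$ch655_au - scan$truth$baseline$ch655_au
    # apex can fall up to half a sample off the event time
    expect_equal(max(corrected), ev$amplitude_au, tolerance = 5e-3)
    apex_t <- scan$traces$time_s[which.max(corrected)]
    expect_lt(abs(apex_t - ev$time_s), 1 / sp$sample_rate)
    # analytic Gaussian area stored as truth
    expect_equal(ev$area_aus, ev$amplitude_au * ev$width_s * sqrt(2 * pi))
    break
  }
  expect_true(found)
})

test_that("identical spec and seed reproduce a scan bit for bit", {
  sp <- quiet_spec(seed = 99)
  a <- generate_scan(sp)
  b <- generate_scan(sp)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$events, b$truth$events)

  c <- generate_scan(quiet_spec(seed = 100))
  expect_false(identical(a$truth$events$time_s, c$truth$events$time_s))
})

test_that("without crosstalk the channels are generated independently", {
  sp1 <- quiet_spec(seed = 4,
                    amplitude_mean = c(ch605_au = 15, ch655_au = 6))
  sp2 <- quiet_spec(seed = 4,
                    amplitude_mean = c(ch605_au = 60, ch655_au = 6))
  a <- generate_scan(sp1)
  b <- generate_scan(sp2)
  expect_identical(a$traces$ch655_au, b$traces$ch655_au)
  expect_false(identical(a$traces$ch605_au, b$traces$ch605_au))
})

test_that("crosstalk injects a scaled copy of the other channel's pulses", {
  base0 <- list(ch605_au = 0, ch655_au = 0)
  sp_id <- quiet_spec(seed = 8, noise_sd = 0, baseline_coeffs = base0,
                      contaminant_rate = 0)
  xt <- matrix(c(1, 0.1, 0.2, 1), 2, 2, byrow = TRUE)
  sp_xt <- quiet_spec(seed = 8, noise_sd = 0, baseline_coeffs = base0,
                      contaminant_rate = 0, crosstalk = xt)
  pure <- generate_scan(sp_id)$traces
  mixed <- generate_scan(sp_xt)$traces
  expect_equal(mixed$ch605_au, pure$ch605_au + 0.1 * pure$ch655_au)
  expect_equal(mixed$ch655_au, pure$ch655_au + 0.2 * pure$ch605_au)
})

test_that("amplitude model is flat at blank and increasing in concentration", {
  amps <- amplitude_from_concentration(c(0, 10, 40, 80, 100), "glucagon")
  expect_equal(amps[1],
               analyte_signal_defaults()$blank_amplitude_au[
                 analyte_signal_defaults()$analyte == "glucagon"])
  expect_true(all(diff(amps) > 0))
  expect_error(amplitude_from_concentration(10, "cortisol"), "unknown analyte")
})

test_that("experiments order mean amplitudes by concentration within channel", {
  pairs <- tibble::tibble(insulin_pM = c(1000, 400, 100, 200),
                          glucagon_pM = c(10, 40, 100, 80))
  ex <- generate_experiment(pairs, quiet_spec(seed = 21),
                            scans_per_sample = 1, interleave_blanks = TRUE)
  expect_equal(nrow(ex$truth$samples), 8)
  expect_true(all(ex$truth$samples$blank == rep(c(TRUE, FALSE), 4)))

  ev <- dplyr::left_join(ex$truth$events, ex$truth$samples, by = "scan")
  mean_amp <- ev |>
    dplyr::filter(kind == "bead", channel == "ch655_au", !blank) |>
    dplyr::group_by(insulin_pM) |>
    dplyr::summarise(amp = mean(amplitude_au), .groups = "drop") |>
    dplyr::arrange(insulin_pM)
  expect_true(all(diff(mean_amp$amp) > 0))

  # scans tile the time axis contiguously
  expect_equal(ex$truth$samples$start_s, (0:7) * 30)
})

test_that("blank-only experiments draw from the background distribution", {
  ex <- generate_experiment(tibble::tibble(insulin_pM = 0, glucagon_pM = 0),
                            quiet_spec(seed = 31), scans_per_sample = 2)
  ev <- ex$truth$events[ex$truth$events$kind == "bead", ]
  defs <- analyte_signal_defaults()
  for (i in seq_len(nrow(defs))) {
    ch <- default_channel_map()$channel[default_channel_map()$analyte ==
                                          defs$analyte[i]]
    amps <- ev$amplitude_au[ev$channel == ch]
    expect_equal(mean(amps), defs$blank_amplitude_au[i], tolerance = 0.25)
  }
  expect_error(
    generate_experiment(tibble::tibble(insulin_pM = 1, cortisol_pM = 2),
                        quiet_spec()),
    "insulin_pM|glucagon_pM|unknown")
})

test_that("repeated experiment generation is deterministic", {
  samples <- tibble::tibble(insulin_pM = c(0, 400), glucagon_pM = c(0, 40))
  a <- generate_experiment(samples, quiet_spec(seed = 77))
  b <- generate_experiment(samples, quiet_spec(seed = 77))
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("trace export round-trips through the delimited format", {
  scan <- generate_scan(quiet_spec(seed = 3, duration = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(scan, path)
  back <- read_traces(path)
  expect_identical(as.data.frame(back), as.data.frame(scan$traces))
})
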