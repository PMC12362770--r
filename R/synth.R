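#' Default channel / analyte assignment
#'
#' The standard two-channel layout: the 605 nm QDot channel reads glucagon and
#' the 655 nm QDot channel reads insulin, both excited by a single 405 nm
#' laser.
#'
#' @return A tibble with columns `channel`, `qdot`, `analyte`.
#' @examples
#' default_channel_map()
#' @export
default_channel_map <- function() {
  tibble(channel = c("ch605_au", "ch655_au"),
         qdot = c(605L, 655L),
         analyte = c("glucagon", "insulin"))
}

validate_channel_map <- function(channel_map) {
  req <- c("channel", "analyte")
  if (!all(req %in% names(channel_map))) {
    abort("`channel_map` needs columns `channel` and `analyte`")
  }
  if (anyDuplicated(channel_map$channel) || anyDuplicated(channel_map$analyte)) {
    abort("`channel_map` must be a bijection between channels and analytes")
  }
  channel_map
}

#' Per-analyte signal model defaults
#'
#' Blank (background) mean pulse amplitude and fluorescence gain for each
#' analyte. Together with the binding kinetics these set the expected pulse
#' amplitude at a given analyte concentration via [amplitude_from_concentration()].
#' Defaults place blank and spiked amplitudes inside the instrument's typical
#' per-concentration ranges (insulin blanks of a few a.u. rising to tens of
#' a.u. at 1000 pM; glucagon blanks of 10-20 a.u. rising to tens-to-hundreds
#' at 100 pM).
#'
#' @return A tibble with columns `analyte`, `blank_amplitude_au`,
#'   `gain_au_per_M`.
#' @export
analyte_signal_defaults <- function() {
  tibble(analyte = c("glucagon", "insulin"),
         blank_amplitude_au = c(15, 6),
         gain_au_per_M = c(1e15, 1e14))
}

#' Expected pulse amplitude at a given analyte concentration
#'
#' Bridges the kinetics and trace-generation layers: runs the sandwich-binding
#' simulation for `t_incubation` seconds at each concentration and maps the
#' resulting sandwich-complex concentration to a mean bead-pulse amplitude,
#' `blank + gain * [sandwich](t_incubation)`.
#'
#' @param conc_pM Analyte concentration(s) in pM (vectorised).
#' @param analyte Analyte name, matched against `signal_defaults$analyte`.
#' @param params A [kinetics_params()] object (its `A` is ignored here; the
#'   analyte `gain_au_per_M` plays that role).
#' @param t_incubation On-chip incubation time, seconds.
#' @param signal_defaults Per-analyte blank amplitude and gain; see
#'   [analyte_signal_defaults()].
#' @return Numeric vector of mean amplitudes, a.u.
#' @examples
#' amplitude_from_concentration(c(0, 100, 1000), "insulin")
#' @export
amplitude_from_concentration <- function(conc_pM, analyte,
                                         params = kinetics_params(),
                                         t_incubation = 30,
                                         signal_defaults = analyte_signal_defaults()) {
  row <- signal_defaults[signal_defaults$analyte == analyte, ]
  if (nrow(row) != 1L) stopf("unknown analyte `%s`", analyte)
  if (any(conc_pM < 0)) abort("concentrations must be >= 0")
  vapply(conc_pM, function(cp) {
    if (cp == 0) return(row$blank_amplitude_au)
    st <- simulate_binding(params, antigen0 = cp * 1e-12,
                           t_end = t_incubation, n_steps = 200)
    row$blank_amplitude_au + row$gain_au_per_M * st$sandwich[nrow(st)]
  }, numeric(1))
}

#' Specification of a synthetic dual-channel scan
#'
#' Describes everything the trace generator needs to emulate one optical scan
#' of beads transiting the detection channel: Poisson bead arrivals, Gaussian
#' transit pulses, multiplicative per-bead amplitude variability from the
#' bead's height in the channel, polynomial baseline drift, white detector
#' noise, spectral crosstalk between the two QDot channels, bead loss in the
#' upstream washing stage, and a low rate of small contaminant events from
#' residual blood cells.
#'
#' Defaults emulate the instrument's operating point: 60 s scans sampled at
#' 1 kHz, ~1 bead/s so that a 30 s frame holds ~30 pulses, 50 ms (Gaussian
#' sigma) transit pulses, 80% bead recovery (`bead_loss = 0.2`) and >90%
#' event purity (`contaminant_rate = 0.1` against `event_rate = 1`). The
#' white-noise floor (0.2 a.u.) sits well below the few-a.u. blank bead
#' pulses, as on a band-limited preamplifier/oscilloscope chain; the
#' relative amplitude filter in the analysis stage assumes this separation.
#'
#' @param duration Scan duration, s.
#' @param sample_rate Sampling rate, Hz. Must resolve the mean pulse width
#'   with at least 8 samples.
#' @param event_rate Bead arrival rate, events/s (Poisson).
#' @param pulse_width_mean,pulse_width_sd Mean and SD of the Gaussian pulse
#'   width parameter (sigma), s.
#' @param amplitude_mean Named vector of mean pulse amplitude per channel,
#'   a.u.; names must match the trace channel columns. Typically produced
#'   from analyte concentrations via [amplitude_from_concentration()].
#' @param height_cv Coefficient of variation of the multiplicative lognormal
#'   per-bead height factor (mean 1).
#' @param baseline_coeffs Named list (per channel) of polynomial coefficients
#'   `c(a0, a1, ...)` giving baseline `a0 + a1 t + ...` in a.u. vs seconds.
#' @param noise_sd SD of additive white detector noise, a.u.
#' @param crosstalk 2x2 mixing matrix applied to the noiseless event
#'   component; entry `[j, k]` is the fraction of channel `k` signal appearing
#'   in channel `j`. Off-diagonals must be in `[0, 1)`.
#' @param bead_loss Fraction of bead events lost upstream, in `[0, 1]`.
#' @param contaminant_rate Spurious small events per second.
#' @param contaminant_amplitude Mean amplitude of contaminant events, a.u.
#' @param seed Integer seed; identical spec + seed reproduce the scan
#'   bit-for-bit.
#'
#' @return An object of class `synth_spec`.
#' @examples
#' sp <- synth_spec(duration = 30, seed = 7)
#' sp$event_rate
#' @export
synth_spec <- function(duration = 60, sample_rate = 1000, event_rate = 1,
                       pulse_width_mean = 0.05, pulse_width_sd = 0.01,
                       amplitude_mean = c(ch605_au = 15, ch655_au = 6),
                       height_cv = 0.25,
                       baseline_coeffs = list(ch605_au = c(2, 0.01),
                                              ch655_au = c(2, 0.01)),
                       noise_sd = 0.2,
                       crosstalk = diag(2),
                       bead_loss = 0.2,
                       contaminant_rate = 0.1,
                       contaminant_amplitude = 2,
                       seed = 1L) {
  sp <- list(duration = duration, sample_rate = sample_rate,
             event_rate = event_rate, pulse_width_mean = pulse_width_mean,
             pulse_width_sd = pulse_width_sd, amplitude_mean = amplitude_mean,
             height_cv = height_cv, baseline_coeffs = baseline_coeffs,
             noise_sd = noise_sd, crosstalk = crosstalk, bead_loss = bead_loss,
             contaminant_rate = contaminant_rate,
             contaminant_amplitude = contaminant_amplitude,
             seed = as.integer(seed))
  if (sp$duration < 0 || sp$sample_rate <= 0 || sp$event_rate < 0) {
    abort("`duration`, `sample_rate` must be positive; `event_rate` >= 0")
  }
  if (sp$pulse_width_mean <= 0) abort("`pulse_width_mean` must be > 0")
  if (sp$sample_rate * sp$pulse_width_mean < 8) {
    abort("`sample_rate` too low: need at least 8 samples per mean pulse width")
  }
  if (sp$height_cv < 0 || sp$noise_sd < 0) {
    abort("`height_cv` and `noise_sd` must be >= 0")
  }
  if (is.null(names(sp$amplitude_mean)) || any(names(sp$amplitude_mean) == "")) {
    abort("`amplitude_mean` must be a named per-channel vector")
  }
  nch <- length(sp$amplitude_mean)
  if (!is.matrix(sp$crosstalk) || any(dim(sp$crosstalk) != nch)) {
    abort("`crosstalk` must be a square matrix matching the channel count")
  }
  off <- sp$crosstalk[row(sp$crosstalk) != col(sp$crosstalk)]
  if (any(off < 0 | off >= 1)) abort("off-diagonal crosstalk must be in [0, 1)")
  if (sp$bead_loss < 0 || sp$bead_loss > 1) abort("`bead_loss` must be in [0, 1]")
  if (sp$contaminant_rate < 0) abort("`contaminant_rate` must be >= 0")
  if (!setequal(names(sp$baseline_coeffs), names(sp$amplitude_mean))) {
    abort("`baseline_coeffs` names must match `amplitude_mean` names")
  }
  structure(sp, class = "synth_spec")
}

# mean-1 lognormal multiplier with a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

polyval_asc <- function(coefs, t) {
  y <- rep(0, length(t))
  for (k in seq_along(coefs)) y <- y + coefs[k] * t^(k - 1)
  y
}

# Draw one channel's events and noise under its own RNG substream, so that a
# change to the other channel's amplitude never perturbs this channel.
draw_channel_events <- function(sp, ch_index) {
  amp_mean <- sp$amplitude_mean[[ch_index]]
  events <- with_private_seed(derive_seed(sp$seed, 1L, ch_index), {
    n_raw <- rpois(1, sp$event_rate * sp$duration)
    keep <- if (n_raw > 0) runif(n_raw) >= sp$bead_loss else logical(0)
    t_bead <- runif(n_raw, 0, sp$duration)[keep]
    h_bead <- rlnorm_cv(sum(keep), sp$height_cv)
    w_bead <- pmax(rnorm(sum(keep), sp$pulse_width_mean, sp$pulse_width_sd),
                   sp$pulse_width_mean / 10)
    n_con <- rpois(1, sp$contaminant_rate * sp$duration)
    t_con <- runif(n_con, 0, sp$duration)
    h_con <- rlnorm_cv(n_con, sp$height_cv)
    w_con <- pmax(rnorm(n_con, sp$pulse_width_mean, sp$pulse_width_sd),
                  sp$pulse_width_mean / 10)
    tibble(
      time_s = c(t_bead, t_con),
      amplitude_au = c(amp_mean * h_bead, sp$contaminant_amplitude * h_con),
      width_s = c(w_bead, w_con),
      kind = rep(c("bead", "contaminant"), c(sum(keep), n_con))
    )
  })
  events <- events[order(events$time_s), , drop = FALSE]
  events$area_aus <- events$amplitude_au * events$width_s * sqrt(2 * pi)
  events
}

draw_channel_noise <- function(sp, ch_index, n) {
  if (sp$noise_sd == 0) return(rep(0, n))
  with_private_seed(derive_seed(sp$seed, 2L, ch_index),
                    rnorm(n, 0, sp$noise_sd))
}

sum_pulses <- function(t, events) {
  y <- rep(0, length(t))
  if (nrow(events) == 0) return(y)
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  for (i in seq_len(nrow(events))) {
    ti <- events$time_s[i]; wi <- events$width_s[i]; ai <- events$amplitude_au[i]
    lo <- max(1L, floor((ti - 6 * wi - t[1]) / dt) + 1L)
    hi <- min(length(t), ceiling((ti + 6 * wi - t[1]) / dt) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + ai * exp(-(t[idx] - ti)^2 / (2 * wi^2))
  }
  y
}

#' Generate one synthetic dual-channel scan
#'
#' Builds each channel as `baseline(t) + sum of Gaussian bead pulses + white
#' noise`, with the noiseless pulse components of the two channels mixed by
#' the crosstalk matrix before baseline and noise are added. Each channel's
#' random draws come from an RNG substream derived from `(seed, channel)`, so
#' the same spec and seed reproduce the scan exactly, and changing one
#' channel's amplitude leaves the other channel's trace untouched when
#' crosstalk is the identity.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `bead_scan` with elements:
#'   * `traces`: tibble `time_s` plus one a.u. column per channel,
#'   * `truth`: list with `events` (per-event channel, time, amplitude, width,
#'     analytic area, kind), `baseline` (tibble on the same grid), and `spec`.
#' @examples
#' scan <- generate_scan(synth_spec(duration = 10, seed = 42))
#' nrow(scan$truth$events)
#' @export
generate_scan <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  channels <- names(spec$amplitude_mean)
  n <- max(1L, round(spec$duration * spec$sample_rate))
  t <- seq(0, by = 1 / spec$sample_rate, length.out = n)

  ev_list <- lapply(seq_along(channels), function(i) {
    ev <- draw_channel_events(spec, i)
    ev$channel <- channels[i]
    ev
  })
  pulse_mat <- vapply(ev_list, function(ev) sum_pulses(t, ev), numeric(n))
  mixed <- pulse_mat %*% t(spec$crosstalk)

  base_mat <- vapply(channels,
                     function(ch) polyval_asc(spec$baseline_coeffs[[ch]], t),
                     numeric(n))
  noise_mat <- vapply(seq_along(channels),
                      function(i) draw_channel_noise(spec, i, n), numeric(n))

  traces <- as_tibble(as.data.frame(base_mat + mixed + noise_mat))
  names(traces) <- channels
  traces <- dplyr::bind_cols(tibble(time_s = t), traces)

  baseline <- as_tibble(as.data.frame(base_mat))
  names(baseline) <- channels
  baseline <- dplyr::bind_cols(tibble(time_s = t), baseline)

  events <- dplyr::bind_rows(ev_list)
  events <- events[, c("channel", "time_s", "amplitude_au", "width_s",
                       "area_aus", "kind")]
  structure(list(traces = traces,
                 truth = list(events = as_tibble(events), baseline = baseline,
                              spec = spec)),
            class = "bead_scan")
}

#' Generate a multi-sample synthetic experiment
#'
#' Emits one or more scans per sample in sequence, concatenated on a common
#' time axis, with the per-channel mean pulse amplitude for each sample
#' derived from its analyte concentrations through the binding-kinetics
#' amplitude model. Blank (0 pM) wash samples can be interleaved between
#' consecutive samples, mirroring how wash blood is run between spiked
#' samples on the instrument.
#'
#' @param samples A data frame with one row per sample and one concentration
#'   column per analyte, named `<analyte>_pM` for every analyte in
#'   `channel_map` (e.g. `insulin_pM`, `glucagon_pM`).
#' @param spec A [synth_spec()] template; `amplitude_mean` is overwritten per
#'   sample and `seed` is re-derived per scan.
#' @param channel_map Channel/analyte assignment; see [default_channel_map()].
#' @param scans_per_sample Number of consecutive scans per sample.
#' @param interleave_blanks Insert a blank sample between consecutive samples
#'   (and before the first one).
#' @param params Kinetics parameters for the amplitude model.
#' @param signal_defaults Per-analyte blank amplitude and gain.
#' @param t_incubation Incubation time fed to the amplitude model, s.
#' @return A list of class `bead_experiment` with `traces` (concatenated),
#'   `truth$events` (with `scan` index), `truth$samples` (one row per scan:
#'   scan index, start/end, per-analyte concentration, `blank` flag), and
#'   `truth$spec`.
#' @examples
#' samples <- tibble::tibble(insulin_pM = c(0, 400), glucagon_pM = c(0, 40))
#' ex <- generate_experiment(samples, synth_spec(duration = 5, seed = 3))
#' ex$truth$samples
#' @export
generate_experiment <- function(samples, spec = synth_spec(),
                                channel_map = default_channel_map(),
                                scans_per_sample = 1,
                                interleave_blanks = FALSE,
                                params = kinetics_params(),
                                signal_defaults = analyte_signal_defaults(),
                                t_incubation = 30) {
  stopifnot(inherits(spec, "synth_spec"))
  channel_map <- validate_channel_map(channel_map)
  samples <- as_tibble(samples)
  conc_cols <- paste0(channel_map$analyte, "_pM")
  missing <- setdiff(conc_cols, names(samples))
  if (length(missing) > 0) {
    stopf("`samples` lacks concentration column(s): %s",
          paste(missing, collapse = ", "))
  }
  extra <- setdiff(grep("_pM$", names(samples), value = TRUE), conc_cols)
  if (length(extra) > 0) {
    stopf("unknown analyte column(s) in `samples`: %s",
          paste(extra, collapse = ", "))
  }

  if (interleave_blanks) {
    blank <- samples[1, ]
    blank[, conc_cols] <- 0
    rows <- list()
    for (i in seq_len(nrow(samples))) {
      rows <- c(rows, list(blank), list(samples[i, ]))
    }
    samples <- dplyr::bind_rows(rows)
  }

  # amplitude per analyte, cached across repeated concentrations
  amp_for <- function(analyte, conc) {
    amplitude_from_concentration(conc, analyte, params = params,
                                 t_incubation = t_incubation,
                                 signal_defaults = signal_defaults)
  }
  amp_cache <- list()
  scan_idx <- 0L
  traces_list <- list(); events_list <- list(); sample_rows <- list()
  for (i in seq_len(nrow(samples))) {
    amps <- vapply(seq_len(nrow(channel_map)), function(k) {
      key <- paste(channel_map$analyte[k], samples[[conc_cols[k]]][i])
      if (is.null(amp_cache[[key]])) {
        amp_cache[[key]] <<- amp_for(channel_map$analyte[k],
                                     samples[[conc_cols[k]]][i])
      }
      amp_cache[[key]]
    }, numeric(1))
    names(amps) <- channel_map$channel
    for (s in seq_len(scans_per_sample)) {
      scan_idx <- scan_idx + 1L
      sp_i <- spec
      sp_i$amplitude_mean <- amps
      sp_i$seed <- derive_seed(spec$seed, 3L, scan_idx)
      scan <- generate_scan(sp_i)
      offset <- (scan_idx - 1L) * spec$duration
      tr <- scan$traces; tr$time_s <- tr$time_s + offset
      ev <- scan$truth$events; ev$time_s <- ev$time_s + offset
      ev$scan <- scan_idx
      traces_list[[scan_idx]] <- tr
      events_list[[scan_idx]] <- ev
      row <- tibble(scan = scan_idx, start_s = offset,
                    end_s = offset + spec$duration,
                    blank = all(samples[i, conc_cols] == 0))
      for (k in seq_len(nrow(channel_map))) {
        row[[conc_cols[k]]] <- samples[[conc_cols[k]]][i]
      }
      sample_rows[[scan_idx]] <- row
    }
  }
  structure(list(traces = dplyr::bind_rows(traces_list),
                 truth = list(events = dplyr::bind_rows(events_list),
                              samples = dplyr::bind_rows(sample_rows),
                              spec = spec)),
            class = "bead_experiment")
}

#' Export dual-channel traces as delimited text
#'
#' Writes the canonical `time_s,ch605_au,ch655_au` format read back by
#' [read_traces()]. Doubles are written with shortest round-trippable
#' precision, so export/import is lossless.
#'
#' @param traces A tibble with `time_s` plus one column per channel, or a
#'   `bead_scan` / `bead_experiment` object.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, delim = ",") {
  if (inherits(traces, c("bead_scan", "bead_experiment"))) traces <- traces$traces
  stopifnot("time_s" %in% names(traces))
  # 17 significant digits: every double survives the text round trip exactly
  out <- as_tibble(lapply(traces, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }))
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
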