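#' Extract one channel from a multi-channel trace table
#'
#' @param traces Tibble with `time_s` and per-channel a.u. columns.
#' @param channel Channel column name, e.g. `"ch655_au"`.
#' @return A single-channel trace: tibble with `time_s`, `signal_au`,
#'   `channel`.
#' @examples
#' scan <- generate_scan(synth_spec(duration = 5, seed = 1))
#' tr <- trace_channel(scan$traces, "ch655_au")
#' @export
trace_channel <- function(traces, channel) {
  if (!channel %in% names(traces)) stopf("no channel column `%s`", channel)
  tibble(time_s = traces$time_s, signal_au = traces[[channel]],
         channel = channel)
}

check_trace <- function(trace) {
  if (!all(c("time_s", "signal_au") %in% names(trace))) {
    abort("a trace needs columns `time_s` and `signal_au`")
  }
  if (nrow(trace) == 0) return(invisible(trace))
  if (any(!is.finite(trace$signal_au))) abort("trace contains non-finite values")
  dt <- diff(trace$time_s)
  if (length(dt) > 0 && (any(dt <= 0) ||
      max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt))) {
    abort("trace time grid must be strictly increasing and uniform")
  }
  invisible(trace)
}

#' Iterative polynomial baseline estimation
#'
#' Estimates the slowly varying baseline under a train of positive pulses by
#' iterative polynomial regression: fit a polynomial of the given degree to
#' the working signal, clip the working signal to the fit wherever it exceeds
#' the fit (suppressing the peaks), and refit until the coefficient vector
#' changes by less than `tol` or `max_iter` is reached. The returned series
#' is the final polynomial evaluated on the trace's time grid.
#'
#' Time is rescaled to \[-1, 1\] internally for numerical conditioning; this
#' does not affect the returned values.
#'
#' @param trace Single-channel trace (columns `time_s`, `signal_au`).
#' @param degree Polynomial degree (>= 0). Degree 3 absorbs the drifts seen
#'   on the instrument without eating into 50 ms pulses.
#' @param max_iter Maximum clip-and-refit iterations.
#' @param tol Relative tolerance on the coefficient-vector change.
#' @param recenter Shift the converged polynomial by the median residual.
#'   The clip-and-refit equilibrium settles near the lower envelope of the
#'   detector noise (clipping only ever pulls the fit down); with peaks
#'   occupying well under half the samples, the median residual is a robust
#'   estimate of that offset, and adding it back centres the baseline in the
#'   noise band so corrected amplitudes and areas are unbiased.
#' @return Numeric vector of baseline values, same length as the trace.
#' @examples
#' scan <- generate_scan(synth_spec(duration = 10, seed = 1))
#' bl <- estimate_baseline(trace_channel(scan$traces, "ch655_au"))
#' @export
estimate_baseline <- function(trace, degree = 3, max_iter = 100, tol = 1e-6,
                              recenter = TRUE) {
  check_trace(trace)
  n <- nrow(trace)
  if (n == 0) return(numeric(0))
  degree <- as.integer(degree)
  if (degree < 0) abort("`degree` must be >= 0")
  if (max_iter < 1) abort("`max_iter` must be >= 1")
  if (degree >= n) abort("`degree` must be smaller than the number of samples")

  tt <- trace$time_s
  span <- diff(range(tt))
  x <- if (span > 0) 2 * (tt - min(tt)) / span - 1 else rep(0, n)
  X <- outer(x, 0:degree, `^`)
  # least-squares projector, reused across iterations (X is fixed; on the
  # [-1,1] scaled abscissa the normal equations are well conditioned for the
  # low degrees used here)
  proj <- solve(crossprod(X), t(X))

  w <- trace$signal_au
  beta_prev <- NULL
  for (it in seq_len(max_iter)) {
    beta <- drop(proj %*% w)
    yhat <- drop(X %*% beta)
    if (!is.null(beta_prev) &&
        max(abs(beta - beta_prev)) <= tol * max(1, max(abs(beta)))) {
      break
    }
    beta_prev <- beta
    w <- pmin(w, yhat)
  }
  base <- drop(X %*% beta)
  if (recenter) base <- base + stats::median(trace$signal_au - base)
  base
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Topographic prominence of the local maximum at index i, capped at `cap`:
# the height of the apex above the higher of the two minima separating it
# from taller terrain. The walk stops early once the drop on a side reaches
# `cap`, so testing prominence against a threshold stays cheap.
peak_prominence <- function(y, i, cap = Inf) {
  v <- y[i]
  side_drop <- function(step) {
    n <- length(y)
    m <- v
    j <- i
    while ((j + step) >= 1 && (j + step) <= n && y[j + step] <= v) {
      j <- j + step
      if (y[j] < m) {
        m <- y[j]
        if (v - m >= cap) return(cap)
      }
    }
    v - m
  }
  min(side_drop(-1L), side_drop(1L), cap)
}

#' Detect bead-transit peaks in a baseline-corrected trace
#'
#' Finds local maxima of the baseline-corrected signal and keeps those whose
#' amplitude exceeds `rel_threshold` times the largest amplitude in the scan
#' (the relative noise-rejection rule: anything at or below 10% of the
#' maximum peak amplitude is treated as noise by default). Apexes closer than
#' `min_separation` are collapsed to the higher one (ties keep the earlier
#' apex), reflecting one bead producing one pulse. Each retained peak gets
#' integration boundaries where the corrected signal falls to `base_frac` of
#' the apex amplitude (effectively the peak base), truncated at the midpoint
#' to an adjacent retained apex when pulses overlap, and its area by
#' trapezoidal integration ([peak_area()]).
#'
#' @param trace Single-channel trace (columns `time_s`, `signal_au`).
#' @param baseline Baseline values on the same grid; estimated with
#'   [estimate_baseline()] defaults when `NULL`.
#' @param rel_threshold Fraction of the per-scan maximum amplitude below
#'   which local maxima are rejected as noise.
#' @param min_separation Minimum apex separation, s; defaults to one mean
#'   pulse width (50 ms).
#' @param base_frac Fraction of apex amplitude defining the peak base
#'   (boundaries placed where the signal has lost `1 - base_frac` of its
#'   prominence).
#' @param prom_frac Minimum topographic prominence of a retained apex, as a
#'   fraction of its amplitude. A free-standing transit pulse has prominence
#'   equal to its amplitude; noise bumps riding another pulse's flank have
#'   near-zero prominence and are rejected. Set to 0 to disable.
#' @param noise_k Noise-referred amplitude floor: apexes must also exceed
#'   `noise_k` times the MAD of the baseline-corrected signal (a robust
#'   noise-scale estimate). Set to 0 to disable.
#' @return A tibble of class `peak_table`, one row per retained peak, sorted
#'   by apex time: `apex_index`, `apex_time_s`, `amplitude_au`,
#'   `left_time_s`, `right_time_s`, `width_s`, `area_aus`.
#' @examples
#' scan <- generate_scan(synth_spec(duration = 10, seed = 1))
#' tr <- trace_channel(scan$traces, "ch655_au")
#' detect_peaks(tr)
#' @export
detect_peaks <- function(trace, baseline = NULL, rel_threshold = 0.10,
                         min_separation = 0.05, base_frac = 0.01,
                         prom_frac = 0.5, noise_k = 5) {
  check_trace(trace)
  empty <- tibble(apex_index = integer(0), apex_time_s = numeric(0),
                  amplitude_au = numeric(0), left_time_s = numeric(0),
                  right_time_s = numeric(0), width_s = numeric(0),
                  area_aus = numeric(0))
  class(empty) <- c("peak_table", class(empty))
  if (nrow(trace) < 3) return(empty)
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  if (length(baseline) != nrow(trace)) {
    abort("`baseline` must be on the same grid as `trace`")
  }
  corrected <- trace$signal_au - baseline
  apex <- local_maxima(corrected)
  apex <- apex[corrected[apex] > 0]
  if (length(apex) == 0 || max(corrected[apex]) <= 0) return(empty)

  amp <- corrected[apex]
  # the relative rule presumes pulses stand clear of the noise band, so a
  # noise-referred floor (MAD of the corrected signal is robust to the
  # pulses themselves) backs it up on low-signal scans
  floor_amp <- if (noise_k > 0) noise_k * stats::mad(corrected) else 0
  keep <- amp > pmax(rel_threshold * max(amp), floor_amp)
  apex <- apex[keep]; amp <- amp[keep]
  if (length(apex) == 0) return(empty)

  # a genuine transit pulse rises from and returns to baseline, so its
  # prominence matches its amplitude; noise bumps riding a pulse flank clear
  # the amplitude rule but have near-zero prominence and are dropped here
  if (prom_frac > 0) {
    need <- prom_frac * amp
    promok <- vapply(seq_along(apex), function(k) {
      peak_prominence(corrected, apex[k], cap = need[k]) >= need[k]
    }, logical(1))
    apex <- apex[promok]; amp <- amp[promok]
    if (length(apex) == 0) return(empty)
  }

  # collapse apexes closer than min_separation: keep the higher (tie: earlier)
  if (!is.null(min_separation) && min_separation > 0 && length(apex) > 1) {
    repeat {
      gaps <- diff(trace$time_s[apex])
      j <- which(gaps < min_separation)[1]
      if (is.na(j)) break
      drop_idx <- if (amp[j + 1] > amp[j]) j else j + 1L
      apex <- apex[-drop_idx]; amp <- amp[-drop_idx]
      if (length(apex) < 2) break
    }
  }

  n <- nrow(trace)
  left_idx <- integer(length(apex)); right_idx <- integer(length(apex))
  for (k in seq_along(apex)) {
    thr <- base_frac * amp[k]
    lo_limit <- if (k > 1) ceiling((apex[k - 1] + apex[k]) / 2) else 1L
    i <- apex[k]
    while (i > lo_limit && corrected[i - 1] > thr) i <- i - 1L
    left_idx[k] <- max(i - 1L, lo_limit)
    hi_limit <- if (k < length(apex)) floor((apex[k] + apex[k + 1]) / 2) else n
    i <- apex[k]
    while (i < hi_limit && corrected[i + 1] > thr) i <- i + 1L
    right_idx[k] <- min(i + 1L, hi_limit)
  }

  peaks <- tibble(
    apex_index = apex,
    apex_time_s = trace$time_s[apex],
    amplitude_au = amp,
    left_time_s = trace$time_s[left_idx],
    right_time_s = trace$time_s[right_idx],
    width_s = trace$time_s[right_idx] - trace$time_s[left_idx]
  )
  peaks$area_aus <- vapply(seq_len(nrow(peaks)), function(k) {
    trapz_area(trace$time_s, corrected, left_idx[k], right_idx[k])
  }, numeric(1))
  class(peaks) <- c("peak_table", class(peaks))
  peaks
}

trapz_area <- function(t, corrected, i0, i1) {
  if (i1 <= i0) return(0)
  idx <- i0:i1
  pracma::trapz(t[idx], pmax(corrected[idx], 0))
}

#' Trapezoidal area under one peak
#'
#' Integrates the baseline-corrected signal between a peak's integration
#' boundaries by the trapezoidal rule, clipping negative excursions of the
#' corrected signal at zero.
#'
#' @param trace Single-channel trace.
#' @param baseline Baseline values on the same grid.
#' @param peak A one-row data frame with `left_time_s` and `right_time_s`
#'   (e.g. one row of a [detect_peaks()] result).
#' @return Area in a.u. * s.
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 1, 0.01),
#'                      signal_au = pmax(0, 10 * (1 - abs(seq(0, 1, 0.01) - 0.5) / 0.5)))
#' peak_area(tr, rep(0, nrow(tr)),
#'           tibble::tibble(left_time_s = 0, right_time_s = 1))
#' @export
peak_area <- function(trace, baseline, peak) {
  check_trace(trace)
  stopifnot(nrow(peak) == 1L)
  if (length(baseline) != nrow(trace)) {
    abort("`baseline` must be on the same grid as `trace`")
  }
  if (peak$left_time_s < trace$time_s[1] ||
      peak$right_time_s > trace$time_s[nrow(trace)]) {
    abort("peak boundaries must lie inside the trace")
  }
  corrected <- trace$signal_au - baseline
  i0 <- which.min(abs(trace$time_s - peak$left_time_s))
  i1 <- which.min(abs(trace$time_s - peak$right_time_s))
  trapz_area(trace$time_s, corrected, i0, i1)
}

#' Summarise one scan's peak set
#'
#' Computes the per-scan readout: the peak count, the scan-validity flag, and
#' the mean area under the peaks (`F1`). A scan is valid when every full 30 s
#' window tiling the scan from its start holds at least `min_peaks_per_30s`
#' peaks (at least 10 beads per 30 s frame by default); a trailing partial
#' window is exempt. When a reference value `f0` is supplied, the normalised
#' readout `F_ratio = F1 / f0` is included.
#'
#' @param peaks A [detect_peaks()] result (or any data frame with
#'   `apex_time_s` and `area_aus`).
#' @param window Scan window `c(start, end)` in seconds.
#' @param min_peaks_per_30s Minimum peaks per full 30 s subwindow.
#' @param validity_window_s Length of the validity subwindow, s.
#' @param f0 Optional reference mean area (blank or pre-event scan).
#' @return One-row tibble: `start_s`, `end_s`, `n_peaks`, `valid`, `F1_aus`,
#'   `F_ratio`.
#' @examples
#' pk <- tibble::tibble(apex_time_s = seq(1, 29, length.out = 12),
#'                      area_aus = rep(2, 12))
#' summarize_scan(pk, window = c(0, 30))
#' @export
summarize_scan <- function(peaks, window, min_peaks_per_30s = 10,
                           validity_window_s = 30, f0 = NULL) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  inside <- peaks$apex_time_s >= window[1] & peaks$apex_time_s <= window[2]
  pk <- peaks[inside, , drop = FALSE]
  # a trailing tile within 1% of the nominal width still counts as full, so
  # a scan sampled on [0, 30) is validated like a nominal 30 s scan
  n_full <- floor((window[2] - window[1]) / validity_window_s + 0.01)
  valid <- TRUE
  for (w in seq_len(n_full)) {
    lo <- window[1] + (w - 1) * validity_window_s
    hi <- lo + validity_window_s
    n_w <- sum(pk$apex_time_s >= lo & pk$apex_time_s < hi)
    if (w == n_full) { # last full tile includes its right edge
      n_w <- sum(pk$apex_time_s >= lo & pk$apex_time_s <= hi)
    }
    if (n_w < min_peaks_per_30s) valid <- FALSE
  }
  tibble(start_s = window[1], end_s = window[2], n_peaks = nrow(pk),
         valid = valid,
         F1_aus = if (nrow(pk) >= 1) mean(pk$area_aus) else NA_real_,
         F_ratio = if (!is.null(f0) && nrow(pk) >= 1) mean(pk$area_aus) / f0
                   else NA_real_)
}

#' Plot a trace with its baseline and detected peaks
#'
#' @param trace Single-channel trace.
#' @param peaks Optional [detect_peaks()] result to mark.
#' @param baseline Optional baseline series to draw.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peaks = NULL, baseline = NULL) {
  check_trace(trace)
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$signal_au)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)")
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = trace$time_s, signal_au = baseline),
      colour = "steelblue", linetype = 2)
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    apex <- tibble(time_s = peaks$apex_time_s,
                   signal_au = trace$signal_au[peaks$apex_index])
    p <- p + ggplot2::geom_point(data = apex, colour = "firebrick", size = 1)
  }
  p
}
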