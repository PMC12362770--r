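#' Read dual-channel photodetector traces from delimited text
#'
#' Reads the `time_s,ch605_au,ch655_au` export format (or any delimited file
#' with a time column plus one numeric column per channel), validates the
#' time grid, and returns the trace table. Malformed rows, missing values and
#' non-uniform or non-increasing timestamps are rejected with the offending
#' row numbers.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @param time_col Name of the time column (renamed to `time_s` on return).
#' @param decimal_mark Decimal mark used in the file.
#' @param comment Comment prefix; lines starting with it are skipped.
#' @param grid_tol Relative tolerance on sampling-interval uniformity.
#' @return A tibble with `time_s` plus the channel columns.
#' @export
read_traces <- function(path, delim = ",", time_col = "time_s",
                        decimal_mark = ".", comment = "#", grid_tol = 1e-6) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # columns are read as text and converted with strtod (via as.numeric),
  # which is correctly rounded; fast approximate float parsers can be off by
  # an ulp and would break lossless round-tripping of exported traces
  d <- readr::read_delim(
    path, delim = delim, comment = comment, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()))
  if (!time_col %in% names(d)) stopf("no time column `%s` in %s", time_col, path)
  names(d)[names(d) == time_col] <- "time_s"
  d <- d[, c("time_s", setdiff(names(d), "time_s"))]
  d <- as_tibble(lapply(d, function(col) {
    if (decimal_mark != ".") col <- gsub(decimal_mark, ".", col, fixed = TRUE)
    suppressWarnings(as.numeric(col))
  }))
  finite_row <- rowSums(!vapply(d, is.finite, logical(nrow(d)))) == 0
  na_rows <- which(!finite_row)
  if (length(na_rows) > 0) {
    stopf("malformed, missing or non-finite values at data row(s) %s",
          paste(head(na_rows, 10), collapse = ", "))
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0)) {
    stopf("time column not strictly increasing at data row(s) %s",
          paste(head(which(dt <= 0) + 1L, 10), collapse = ", "))
  }
  med <- stats::median(dt)
  off <- which(abs(dt - med) > grid_tol * med)
  if (length(off) > 0) {
    stopf("non-uniform sampling interval at data row(s) %s",
          paste(head(off + 1L, 10), collapse = ", "))
  }
  d
}

split_scan_windows <- function(t0, t1, scan_duration) {
  starts <- seq(t0, t1, by = scan_duration)
  starts <- starts[starts < t1 - 1e-9]
  tibble(scan = seq_along(starts), start_s = starts,
         end_s = pmin(starts + scan_duration, t1))
}

#' Analyse a multiplexed run end-to-end
#'
#' Orchestrates the full analysis chain: split the traces into fixed
#' wall-clock scan windows (60 s by default), and for every channel in every
#' scan estimate the baseline, detect and filter peaks, integrate peak areas
#' and summarise the scan; then normalise each scan's mean peak area `F1` by
#' the reference `F0` and invert the analyte's calibration curve to a
#' concentration. Channels are processed independently (no crosstalk
#' unmixing). Invalid scans (too few beads) carry no concentration and are
#' flagged; out-of-range ratios are flagged by [invert_4pl()], never clipped.
#'
#' `F0` modes: `"blank_scans"` takes the mean `F1` of designated blank scan
#' indices per channel; `"pre_event"` the mean `F1` of scans ending before
#' `event_time_s`; `"fixed"` uses user-supplied values (named by channel).
#'
#' @param traces Trace tibble (`time_s` + channel columns) or a `bead_scan` /
#'   `bead_experiment`.
#' @param channel_map Channel/analyte assignment ([default_channel_map()]).
#' @param models Named list of [calibrate()] models, one per mapped analyte;
#'   `NULL` to stop after F1/F_ratio (no concentrations).
#' @param scan_duration Scan window length, s.
#' @param f0_mode How the reference `F0` is defined (see Details).
#' @param blank_scans Integer scan indices for `f0_mode = "blank_scans"`.
#' @param event_time_s Event time for `f0_mode = "pre_event"`.
#' @param f0 Named per-channel values for `f0_mode = "fixed"`.
#' @param baseline_degree,rel_threshold,min_separation,min_peaks_per_30s
#'   Signal-analysis settings passed through to the peaks stage.
#' @return An object of class `run_result`: `$scans` (one row per scan per
#'   channel with `n_peaks`, `valid`, `F1_aus`, `F_ratio`, `conc_pM`,
#'   `flag`), `$f0` (per channel), `$channel_map`, `$config`.
#' @examples
#' scan <- generate_scan(synth_spec(duration = 30, seed = 1))
#' res <- analyze_run(scan, scan_duration = 30, f0_mode = "fixed",
#'                    f0 = c(ch605_au = 1, ch655_au = 1))
#' res$scans
#' @export
analyze_run <- function(traces, channel_map = default_channel_map(),
                        models = NULL, scan_duration = 60,
                        f0_mode = c("blank_scans", "pre_event", "fixed"),
                        blank_scans = NULL, event_time_s = NULL, f0 = NULL,
                        baseline_degree = 3, rel_threshold = 0.10,
                        min_separation = 0.05, min_peaks_per_30s = 10) {
  f0_mode <- match.arg(f0_mode)
  if (inherits(traces, c("bead_scan", "bead_experiment"))) traces <- traces$traces
  channel_map <- validate_channel_map(channel_map)
  if (!all(channel_map$channel %in% names(traces))) {
    stopf("traces lack mapped channel(s): %s",
          paste(setdiff(channel_map$channel, names(traces)), collapse = ", "))
  }
  if (!is.null(models)) {
    missing <- setdiff(channel_map$analyte, names(models))
    if (length(missing) > 0) {
      stopf("no calibration model for analyte(s): %s",
            paste(missing, collapse = ", "))
    }
  }

  windows <- split_scan_windows(traces$time_s[1],
                                traces$time_s[nrow(traces)], scan_duration)
  scan_rows <- list()
  for (i in seq_len(nrow(windows))) {
    in_win <- traces$time_s >= windows$start_s[i] &
      traces$time_s <= windows$end_s[i] + 1e-9
    for (k in seq_len(nrow(channel_map))) {
      ch <- channel_map$channel[k]
      tr <- tibble(time_s = traces$time_s[in_win],
                   signal_au = traces[[ch]][in_win])
      bl <- estimate_baseline(tr, degree = baseline_degree)
      pk <- detect_peaks(tr, baseline = bl, rel_threshold = rel_threshold,
                         min_separation = min_separation)
      sm <- summarize_scan(pk, window = c(windows$start_s[i], windows$end_s[i]),
                           min_peaks_per_30s = min_peaks_per_30s)
      scan_rows[[length(scan_rows) + 1L]] <- dplyr::bind_cols(
        tibble(scan = windows$scan[i], channel = ch,
               analyte = channel_map$analyte[k]), sm)
    }
  }
  scans <- dplyr::bind_rows(scan_rows)
  if (nrow(scans) == 0 || all(!scans$valid)) {
    warn("no valid scans in this run")
  }

  f0_tbl <- switch(f0_mode,
    blank_scans = {
      if (is.null(blank_scans) || length(blank_scans) == 0) {
        abort("`blank_scans` must name at least one scan index")
      }
      scans |>
        dplyr::filter(.data$scan %in% blank_scans, .data$valid) |>
        dplyr::group_by(.data$channel) |>
        dplyr::summarise(F0 = mean(.data$F1_aus, na.rm = TRUE), .groups = "drop")
    },
    pre_event = {
      if (is.null(event_time_s)) abort("`event_time_s` is required")
      scans |>
        dplyr::filter(.data$end_s <= event_time_s, .data$valid) |>
        dplyr::group_by(.data$channel) |>
        dplyr::summarise(F0 = mean(.data$F1_aus, na.rm = TRUE), .groups = "drop")
    },
    fixed = {
      if (is.null(f0) || is.null(names(f0))) {
        abort("`f0` must be a named per-channel vector")
      }
      tibble(channel = names(f0), F0 = unname(f0))
    })
  if (!all(channel_map$channel %in% f0_tbl$channel) ||
      any(!is.finite(f0_tbl$F0))) {
    abort("could not determine a finite F0 for every channel")
  }

  scans <- scans |>
    dplyr::left_join(f0_tbl, by = "channel") |>
    dplyr::mutate(F_ratio = .data$F1_aus / .data$F0)

  if (!is.null(models)) {
    inv <- purrr::pmap(list(scans$analyte, scans$F_ratio, scans$valid),
      function(an, r, ok) {
        if (!ok || !is.finite(r)) {
          return(tibble(conc_pM = NA_real_, flag = "invalid_scan"))
        }
        invert_4pl(models[[an]], r)[, c("conc_pM", "flag")]
      })
    scans <- dplyr::bind_cols(scans, dplyr::bind_rows(inv))
  } else {
    scans$conc_pM <- NA_real_
    scans$flag <- ifelse(scans$valid, "no_model", "invalid_scan")
  }

  structure(list(scans = scans, f0 = f0_tbl, channel_map = channel_map,
                 config = list(scan_duration = scan_duration,
                               f0_mode = f0_mode,
                               baseline_degree = baseline_degree,
                               rel_threshold = rel_threshold,
                               min_separation = min_separation,
                               min_peaks_per_30s = min_peaks_per_30s)),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d scans x %d channels, %d valid scan-channels\n",
              length(unique(x$scans$scan)), nrow(x$channel_map),
              sum(x$scans$valid)))
  print(tidy(x), n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.run_result <- function(x, ...) {
  x$scans |>
    dplyr::transmute(scan = .data$scan, scan_start_s = .data$start_s,
                     analyte = .data$analyte, n_peaks = .data$n_peaks,
                     valid = .data$valid, F1 = .data$F1_aus,
                     F_ratio = .data$F_ratio, conc_pM = .data$conc_pM,
                     flag = .data$flag)
}

#' @exportS3Method generics::glance
glance.run_result <- function(x, ...) {
  tibble(n_scans = length(unique(x$scans$scan)),
         n_channels = nrow(x$channel_map),
         n_valid = sum(x$scans$valid),
         mean_peaks_per_scan = mean(x$scans$n_peaks))
}

#' @exportS3Method ggplot2::autoplot
autoplot.run_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scan_start_s, y = .data$F1,
                                  colour = .data$analyte)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "scan start (s)", y = expression(F[1] ~ "(a.u." %.% "s)"))
}

#' Write a per-scan JSON report
#'
#' @param result A `run_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(result, path) {
  stopifnot(inherits(result, "run_result"))
  out <- list(config = result$config,
              f0 = as.list(setNames(result$f0$F0, result$f0$channel)),
              scans = tidy(result))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Simulate, calibrate and re-analyse: closed-loop recovery experiment
#'
#' The package's own end-to-end check, runnable on any desktop: for each seed
#' it (1) simulates a multiplexed calibration experiment over a ladder of
#' paired insulin/glucagon concentrations with interleaved blanks, (2)
#' analyses it and fits per-analyte calibration models, (3) simulates an
#' independent test experiment over the standard sample pairs (insulin 1000,
#' 400, 100, 200 pM against glucagon 10, 40, 100, 80 pM) under held-out
#' seeds, and (4) analyses it with the fitted models and compares recovered
#' concentrations against the generator's ground truth.
#'
#' @param seeds Integer vector; one replicate per seed (test seeds are
#'   derived, never shared with calibration).
#' @param calibration_pairs,test_pairs Data frames of paired concentrations
#'   (`insulin_pM`, `glucagon_pM`), one row per sample.
#' @param scans_per_sample Scans simulated per sample.
#' @param spec A [synth_spec()] template (seed is overridden per replicate).
#' @param params Kinetics parameters for the amplitude model.
#' @return An object of class `recovery_report`: `$per_level` (bias and
#'   relative RMSE per analyte and true concentration), `$per_seed`
#'   (rank-order correctness and per-analyte empirical LOD per replicate),
#'   `$estimates` (every scan-level estimate).
#' @examples
#' \donttest{
#' rep <- recovery_experiment(seeds = 1, scans_per_sample = 2)
#' rep$per_level
#' }
#' @export
recovery_experiment <- function(seeds = 1:20,
                                calibration_pairs = tibble(
                                  insulin_pM = c(100, 200, 400, 1000),
                                  glucagon_pM = c(100, 80, 40, 10)),
                                test_pairs = tibble(
                                  insulin_pM = c(1000, 400, 100, 200),
                                  glucagon_pM = c(10, 40, 100, 80)),
                                scans_per_sample = 3,
                                spec = synth_spec(),
                                params = kinetics_params(),
                                min_peaks_per_30s = 10) {
  channel_map <- default_channel_map()
  per_seed <- list(); estimates <- list()
  for (s in seeds) {
    sp_cal <- spec; sp_cal$seed <- derive_seed(s, 11L)
    cal <- generate_experiment(calibration_pairs, spec = sp_cal,
                               scans_per_sample = scans_per_sample,
                               interleave_blanks = TRUE, params = params)
    blank_idx <- cal$truth$samples$scan[cal$truth$samples$blank]
    cal_res <- analyze_run(cal, channel_map = channel_map,
                           scan_duration = spec$duration,
                           f0_mode = "blank_scans", blank_scans = blank_idx,
                           min_peaks_per_30s = min_peaks_per_30s)
    cal_tbl <- cal_res$scans |>
      dplyr::filter(.data$valid) |>
      dplyr::left_join(cal$truth$samples, by = "scan",
                       suffix = c("", ".truth"))
    models <- list()
    for (an in channel_map$analyte) {
      d <- tibble(concentration_pM = cal_tbl[[paste0(an, "_pM")]][cal_tbl$analyte == an],
                  ratio = cal_tbl$F_ratio[cal_tbl$analyte == an])
      models[[an]] <- calibrate(d, analyte = an)
    }

    sp_test <- spec; sp_test$seed <- derive_seed(s, 13L)
    test <- generate_experiment(test_pairs, spec = sp_test,
                                scans_per_sample = scans_per_sample,
                                interleave_blanks = TRUE, params = params)
    blank_idx_t <- test$truth$samples$scan[test$truth$samples$blank]
    res <- analyze_run(test, channel_map = channel_map, models = models,
                       scan_duration = spec$duration,
                       f0_mode = "blank_scans", blank_scans = blank_idx_t,
                       min_peaks_per_30s = min_peaks_per_30s)
    est <- res$scans |>
      dplyr::left_join(test$truth$samples, by = "scan") |>
      dplyr::filter(!.data$blank, .data$valid)
    est$true_pM <- ifelse(est$analyte == "insulin", est$insulin_pM,
                          est$glucagon_pM)
    est$seed <- s
    estimates[[length(estimates) + 1L]] <-
      est[, c("seed", "scan", "analyte", "true_pM", "F1_aus", "F_ratio",
              "conc_pM", "flag")]

    rank_ok <- est |>
      dplyr::group_by(.data$analyte, .data$true_pM) |>
      dplyr::summarise(mean_est = mean(.data$conc_pM), .groups = "drop") |>
      dplyr::group_by(.data$analyte) |>
      dplyr::summarise(
        rank_correct = !anyNA(.data$mean_est) &&
          identical(order(.data$mean_est), order(.data$true_pM)),
        .groups = "drop")
    lods <- tibble(analyte = names(models),
                   lod_pM = vapply(models, function(m) m$lod_pM, numeric(1)))
    per_seed[[length(per_seed) + 1L]] <- rank_ok |>
      dplyr::left_join(lods, by = "analyte") |>
      dplyr::mutate(seed = s, .before = 1)
  }
  estimates <- dplyr::bind_rows(estimates)
  per_level <- estimates |>
    dplyr::group_by(.data$analyte, .data$true_pM) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_est_pM = mean(.data$conc_pM),
      bias_pM = mean(.data$conc_pM - .data$true_pM),
      rel_rmse = sqrt(mean(((.data$conc_pM - .data$true_pM) /
                              .data$true_pM)^2)),
      .groups = "drop")
  structure(list(per_level = per_level,
                 per_seed = dplyr::bind_rows(per_seed),
                 estimates = estimates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$per_level)
  cat(sprintf("  rank order correct: %d / %d analyte-replicates\n",
              sum(x$per_seed$rank_correct), nrow(x$per_seed)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recovery_report <- function(x, ...) x$per_level

#' @exportS3Method generics::glance
glance.recovery_report <- function(x, ...) {
  tibble(n_seeds = length(unique(x$per_seed$seed)),
         rank_order_rate = mean(x$per_seed$rank_correct),
         max_rel_rmse = max(x$per_level$rel_rmse),
         median_lod_insulin_pM =
           stats::median(x$per_seed$lod_pM[x$per_seed$analyte == "insulin"]),
         median_lod_glucagon_pM =
           stats::median(x$per_seed$lod_pM[x$per_seed$analyte == "glucagon"]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = factor(.data$true_pM), y = .data$conc_pM)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~.data$analyte, scales = "free") +
    ggplot2::labs(x = "true concentration (pM)",
                  y = "recovered concentration (pM)")
}
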