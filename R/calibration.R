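#' Four-parameter logistic dose-response function
#'
#' The increasing 4PL form used for calibration,
#' \deqn{y(x) = d_0 + \frac{d_{max} - d_0}{1 + (c_{50}/x)^b},}
#' extended continuously so that `y(0) = d0` for `b > 0`.
#'
#' @param x Concentration(s), pM.
#' @param d0 Lower asymptote (signal ratio at zero concentration).
#' @param dmax Upper asymptote.
#' @param c50 Midpoint concentration, pM (> 0).
#' @param b Slope factor (> 0 for an increasing curve).
#' @return Predicted signal ratio(s).
#' @examples
#' fourpl(c(0, 300, 1e6), d0 = 1, dmax = 3, c50 = 300, b = 1.5)
#' @export
fourpl <- function(x, d0, dmax, c50, b) {
  ifelse(x <= 0, d0, d0 + (dmax - d0) / (1 + (c50 / x)^b))
}

#' Fit a 4PL calibration curve
#'
#' Least-squares fit of the sigmoidal four-parameter logistic model to
#' (concentration, signal-ratio) calibration data, via bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). Initial guesses are
#' `d0 = min(y)`, `dmax = max(y)`, `c50 = median of positive x`, `b = 1`;
#' `c50` and `b` are kept positive by bounds, so the fitted curve is strictly
#' increasing in concentration.
#'
#' A response with essentially no dynamic range (all ratios equal) cannot
#' identify `c50` or `b`; such data yield a flat fit flagged `degenerate`.
#'
#' @param data Data frame with columns `concentration_pM` and `ratio`
#'   (replicates as repeated rows). At least 4 distinct concentrations are
#'   required.
#' @return An object of class `fourpl_fit`: coefficients, fitted values,
#'   residual summary, convergence and degeneracy flags.
#' @examples
#' d <- tibble::tibble(concentration_pM = c(0, 50, 150, 300, 600, 1200),
#'                     ratio = fourpl(c(0, 50, 150, 300, 600, 1200),
#'                                    1, 3, 300, 1.5))
#' coef(fit_4pl(d))
#' @export
fit_4pl <- function(data) {
  data <- as_tibble(data)
  if (!all(c("concentration_pM", "ratio") %in% names(data))) {
    abort("`data` needs columns `concentration_pM` and `ratio`")
  }
  x <- data$concentration_pM
  y <- data$ratio
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0)) {
    abort("calibration data must be finite with concentrations >= 0")
  }
  if (length(unique(x)) < 4) {
    abort("a 4PL fit needs at least 4 distinct concentrations")
  }

  yr <- diff(range(y))
  if (yr <= 1e-8 * max(1, abs(mean(y)))) {
    fit <- structure(list(
      coef = c(d0 = mean(y), dmax = mean(y),
               c50 = stats::median(x[x > 0]), b = 1),
      std_error = c(d0 = NA_real_, dmax = NA_real_, c50 = NA_real_,
                    b = NA_real_),
      data = data, fitted = rep(mean(y), length(y)),
      residuals = y - mean(y), rss = sum((y - mean(y))^2),
      sigma = 0, n = length(y), converged = TRUE, degenerate = TRUE
    ), class = "fourpl_fit")
    return(fit)
  }

  start <- list(d0 = min(y), dmax = max(y),
                c50 = stats::median(x[x > 0]), b = 1)
  xpos <- x[x > 0]
  lower <- c(d0 = min(y) - 10 * yr, dmax = min(y) - 10 * yr,
             c50 = min(xpos) * 1e-3, b = 0.05)
  upper <- c(d0 = max(y) + 10 * yr, dmax = max(y) + 10 * yr,
             c50 = max(xpos) * 1e3, b = 20)
  mod <- tryCatch(
    minpack.lm::nlsLM(ratio ~ fourpl(concentration_pM, d0, dmax, c50, b),
                      data = data, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stopf(paste0("4PL fit did not converge (%s); ",
                   "initial guesses were d0=%.4g dmax=%.4g c50=%.4g b=%.4g"),
            conditionMessage(e), start$d0, start$dmax, start$c50, start$b)
    })
  cf <- coef(mod)
  se <- tryCatch(summary(mod)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  res <- y - fourpl(x, cf["d0"], cf["dmax"], cf["c50"], cf["b"])
  structure(list(
    coef = cf, std_error = se[names(cf)], data = data,
    fitted = y - res, residuals = res, rss = sum(res^2),
    sigma = sqrt(sum(res^2) / max(1, length(y) - 4)), n = length(y),
    converged = TRUE,
    degenerate = unname(cf["dmax"] - cf["d0"]) < 1e-8 * max(1, abs(mean(y)))
  ), class = "fourpl_fit")
}

#' @export
coef.fourpl_fit <- function(object, ...) object$coef

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("<fourpl_fit>", if (x$degenerate) "(degenerate: flat response)", "\n")
  print(round(x$coef, 6))
  cat(sprintf("  n = %d, residual sigma = %.4g\n", x$n, x$sigma))
  invisible(x)
}

#' Predict signal ratios from a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param newdata Numeric vector of concentrations (pM), or a data frame with
#'   a `concentration_pM` column. Defaults to the fitting data.
#' @param ... Unused.
#' @return Numeric vector of predicted ratios.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration_pM
       else if (is.data.frame(newdata)) newdata$concentration_pM
       else newdata
  cf <- object$coef
  unname(fourpl(x, cf["d0"], cf["dmax"], cf["c50"], cf["b"]))
}

#' @exportS3Method generics::tidy
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(x$std_error))
}

#' @exportS3Method generics::glance
glance.fourpl_fit <- function(x, ...) {
  tibble(nobs = x$n, rss = x$rss, sigma = x$sigma,
         converged = x$converged, degenerate = x$degenerate)
}

#' Invert a 4PL curve back to concentration
#'
#' Closed-form inverse of the fitted calibration curve,
#' `x = c50 * ((dmax - d0)/(y - d0) - 1)^(-1/b)`, applied to measured signal
#' ratios. Ratios at or below the lower asymptote map to 0 pM with a
#' `below_range` flag; ratios at or above the upper asymptote are flagged
#' `saturated` (concentration `NA`). Flags are returned, never raised as
#' errors: out-of-range readouts are expected in routine operation.
#'
#' @param model A `fourpl_fit` or [calibrate()] result.
#' @param ratio Numeric vector of measured signal ratios (F1/F0).
#' @return Tibble with columns `ratio`, `conc_pM`, `flag`
#'   (`"ok"`, `"below_range"`, `"saturated"`).
#' @examples
#' d <- tibble::tibble(concentration_pM = c(0, 50, 150, 300, 600, 1200),
#'                     ratio = fourpl(c(0, 50, 150, 300, 600, 1200),
#'                                    1, 3, 300, 1.5))
#' invert_4pl(fit_4pl(d), c(0.9, 2, 3.5))
#' @export
invert_4pl <- function(model, ratio) {
  if (inherits(model, "calibration_model")) model <- model$fit
  stopifnot(inherits(model, "fourpl_fit"))
  cf <- model$coef
  d0 <- unname(cf["d0"]); dmax <- unname(cf["dmax"])
  c50 <- unname(cf["c50"]); b <- unname(cf["b"])
  conc <- rep(NA_real_, length(ratio))
  flag <- rep("ok", length(ratio))
  below <- ratio <= d0
  sat <- ratio >= dmax
  ok <- !below & !sat
  conc[below] <- 0
  flag[below] <- "below_range"
  flag[sat] <- "saturated"
  conc[ok] <- c50 * ((dmax - d0) / (ratio[ok] - d0) - 1)^(-1 / b)
  tibble(ratio = ratio, conc_pM = conc, flag = flag)
}

#' Limit of detection from blank SD and calibration slope
#'
#' The standard `LOD = 3.3 * SD / S`, where `SD` is the standard deviation of
#' blank-replicate signal ratios and `S` the slope of the calibration curve
#' in the low-concentration region.
#'
#' @param blank_sd Standard deviation of blank replicates (>= 0).
#' @param slope Calibration slope, signal ratio per pM (> 0).
#' @return LOD in pM.
#' @examples
#' lod(blank_sd = 1, slope = 3.3)
#' @export
lod <- function(blank_sd, slope) {
  if (!is.numeric(slope) || slope <= 0) abort("`slope` must be > 0")
  if (!is.numeric(blank_sd) || blank_sd < 0) abort("`blank_sd` must be >= 0")
  3.3 * blank_sd / slope
}

#' Build a full calibration model for one analyte
#'
#' Fits the 4PL curve, estimates the blank SD from the 0 pM replicates, the
#' low-range calibration slope, and the limit of detection.
#'
#' The LOD slope is, by default, the ordinary least-squares slope through the
#' blank and the two lowest nonzero concentrations -- the region where the
#' LOD lives; alternatively (`slope_method = "midpoint"`) the analytic 4PL
#' derivative at `c50`, `(dmax - d0) * b / (4 * c50)`.
#'
#' @param data Data frame with columns `concentration_pM`, `ratio` (replicate
#'   rows). Needs >= 4 distinct concentrations and >= 2 blank replicates for
#'   an LOD.
#' @param analyte Optional analyte label carried in the model.
#' @param slope_method `"low_range"` (default) or `"midpoint"`.
#' @return An object of class `calibration_model`: the `fourpl_fit` plus
#'   `blank_sd`, `slope`, `lod_pM` and the label.
#' @examples
#' conc <- rep(c(0, 50, 150, 300, 600), each = 3)
#' set.seed(1)
#' d <- tibble::tibble(concentration_pM = conc,
#'                     ratio = fourpl(conc, 1, 3, 300, 1.5) + rnorm(15, 0, 0.02))
#' m <- calibrate(d, analyte = "insulin")
#' m$lod_pM
#' @export
calibrate <- function(data, analyte = NULL,
                      slope_method = c("low_range", "midpoint")) {
  slope_method <- match.arg(slope_method)
  fit <- fit_4pl(data)
  data <- fit$data
  blanks <- data$ratio[data$concentration_pM == 0]
  blank_sd <- if (length(blanks) >= 2) sd(blanks) else NA_real_
  if (length(blanks) < 2) {
    warn("fewer than 2 blank replicates: blank SD and LOD are NA")
  }

  if (slope_method == "low_range") {
    xs <- sort(unique(data$concentration_pM[data$concentration_pM > 0]))
    low <- c(0, head(xs, 2))
    sub <- data[data$concentration_pM %in% low, ]
    slope <- unname(coef(lm(ratio ~ concentration_pM, data = sub))[2])
  } else {
    cf <- fit$coef
    slope <- unname((cf["dmax"] - cf["d0"]) * cf["b"] / (4 * cf["c50"]))
  }

  lod_pM <- if (is.finite(blank_sd) && is.finite(slope) && slope > 0) {
    lod(blank_sd, slope)
  } else {
    NA_real_
  }
  structure(list(analyte = analyte, fit = fit, blank_sd = blank_sd,
                 slope = slope, slope_method = slope_method, lod_pM = lod_pM),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model%s>\n",
              if (!is.null(x$analyte)) paste0(": ", x$analyte) else ""))
  print(round(x$fit$coef, 6))
  cat(sprintf("  blank SD = %.4g, slope (%s) = %.4g /pM, LOD = %.4g pM\n",
              x$blank_sd, x$slope_method, x$slope, x$lod_pM))
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) object$fit$coef

#' @export
predict.calibration_model <- function(object, newdata = NULL, ...) {
  predict(object$fit, newdata = newdata, ...)
}

#' @exportS3Method generics::tidy
tidy.calibration_model <- function(x, ...) tidy(x$fit, ...)

#' @exportS3Method generics::glance
glance.calibration_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble(blank_sd = x$blank_sd, slope = x$slope,
                          lod_pM = x$lod_pM))
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_model <- function(object, ...) {
  d <- object$fit$data
  xpos <- d$concentration_pM[d$concentration_pM > 0]
  grid <- c(0, exp(seq(log(max(min(xpos) / 4, 1e-3)),
                       log(max(xpos) * 2), length.out = 200)))
  curve <- tibble(concentration_pM = grid,
                  ratio = predict(object, newdata = grid))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_pM, y = .data$ratio)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::labs(x = "concentration (pM)", y = expression(F[1] / F[0]),
                  title = object$analyte)
}

# pseudo-log transform without depending on scales directly
scales_pseudo_log <- function() {
  if (requireNamespace("scales", quietly = TRUE)) {
    scales::pseudo_log_trans(sigma = 1, base = 10)
  } else {
    "identity"
  }
}

#' Restore a calibration model persisted with [write_calibration_model()]
#'
#' Rebuilds a usable `calibration_model` (prediction, inversion, LOD) from
#' the JSON snapshot; fitting diagnostics and the original data are not
#' stored and come back empty.
#'
#' @param path JSON file written by [write_calibration_model()].
#' @return A `calibration_model`.
#' @export
read_calibration_model <- function(path) {
  j <- jsonlite::read_json(path)
  cf <- unlist(j$coef)[c("d0", "dmax", "c50", "b")]
  fit <- structure(list(
    coef = cf, std_error = setNames(rep(NA_real_, 4), names(cf)),
    data = tibble(concentration_pM = numeric(0), ratio = numeric(0)),
    fitted = numeric(0), residuals = numeric(0), rss = NA_real_,
    sigma = NA_real_, n = 0L, converged = TRUE,
    degenerate = isTRUE(j$degenerate)
  ), class = "fourpl_fit")
  structure(list(analyte = j$analyte, fit = fit,
                 blank_sd = j$blank_sd %||% NA_real_,
                 slope = j$slope %||% NA_real_,
                 slope_method = j$slope_method %||% "low_range",
                 lod_pM = j$lod_pM %||% NA_real_),
            class = "calibration_model")
}

#' Read a calibration table from delimited text
#'
#' Expects columns `analyte`, `concentration_pM`, `ratio`.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble.
#' @export
read_calibration_table <- function(path, delim = ",") {
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("analyte", "concentration_pM", "ratio")
  if (!all(need %in% names(d))) {
    stopf("calibration table needs columns: %s", paste(need, collapse = ", "))
  }
  d
}

#' Persist a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  out <- list(analyte = model$analyte, coef = as.list(model$fit$coef),
              blank_sd = model$blank_sd, slope = model$slope,
              slope_method = model$slope_method, lod_pM = model$lod_pM,
              degenerate = model$fit$degenerate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
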