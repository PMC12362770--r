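# Independent oracles and fixture builders used across the suite.

# Brute-force explicit-Euler integration of the two-step sandwich scheme.
# Deliberately naive (fixed step, no solver machinery) so it is independent
# of the deSolve-based implementation it checks.
euler_binding <- function(params, antigen0, t_end, n_steps) {
  dt <- t_end / n_steps
  e <- params$enhancement
  C <- 0; S <- 0
  for (i in seq_len(n_steps)) {
    free <- antigen0 - C - S
    cap_free <- params$cap_sites - C - S
    det_free <- params$det_ab - S
    flux2 <- e * params$kon2 * C * det_free - params$koff2 * S
    dC <- e * params$kon1 * free * cap_free - params$koff1 * C - flux2
    C <- C + dt * dC
    S <- S + dt * flux2
  }
  c(captured = C, sandwich = S)
}

# Closed-form equilibrium of single-step reversible bimolecular binding
# (quadratic binding isotherm): C_eq solves kon*(L0-C)*(R0-C) = koff*C.
isotherm_captured_eq <- function(kon_eff, koff, L0, R0) {
  if (koff == 0) return(min(L0, R0))
  Kd <- koff / kon_eff
  b <- L0 + R0 + Kd
  (b - sqrt(b^2 - 4 * L0 * R0)) / 2
}

# Clean trace builder: Gaussian pulses at given times on a known baseline,
# built directly from the closed-form pulse shape (independent of the
# generator module).
make_pulse_trace <- function(times, amps, sigma, duration = 60,
                             sample_rate = 200, baseline_fun = function(t) 0,
                             noise_sd = 0, seed = NULL) {
  t <- seq(0, duration, by = 1 / sample_rate)
  y <- baseline_fun(t)
  for (k in seq_along(times)) {
    y <- y + amps[k] * exp(-(t - times[k])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  tibble::tibble(time_s = t, signal_au = y)
}

# Small synthetic 4PL calibration table with known parameters.
make_4pl_table <- function(conc, d0 = 1, dmax = 3, c50 = 300, b = 1.5,
                           reps = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(conc, each = reps)
  y <- beadflow::fourpl(conc, d0, dmax, c50, b)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  tibble::tibble(concentration_pM = conc, ratio = y)
}
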