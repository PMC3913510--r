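#' Specify a synthetic chromatographic peak
#'
#' Peaks are Gaussian or exponentially modified Gaussian (EMG), the standard
#' model for tailed chromatographic peaks. Widths are given in seconds, the
#' natural scale for HPLC peak widths; retention time stays in minutes.
#'
#' @param retention_time Apex position in minutes (for `tau = 0`; tailing
#'   shifts the apex slightly right).
#' @param height Peak height of the underlying Gaussian, intensity units.
#' @param sigma Gaussian width in seconds.
#' @param tau Exponential tail time constant in seconds; 0 gives a pure
#'   Gaussian.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(retention_time, height, sigma, tau = 0) {
  if (!is_number(height) || height <= 0) {
    abort_ssr("height must be positive", "ssr_parameter_error")
  }
  if (!is_number(sigma) || sigma <= 0) {
    abort_ssr("sigma must be positive", "ssr_parameter_error")
  }
  if (!is_number(tau) || tau < 0) {
    abort_ssr("tau must be >= 0", "ssr_parameter_error")
  }
  structure(
    list(retention_time = retention_time, height = height,
         sigma = sigma, tau = tau),
    class = "peak_spec"
  )
}

#' Evaluate a peak profile
#'
#' Gaussian `h * exp(-(t - tr)^2 / (2 sigma^2))` when `tau = 0`; for
#' `tau > 0` the EMG closed form
#' `h * (sigma/tau) * sqrt(pi/2) * exp(sigma^2/(2 tau^2) - (t - tr)/tau) *
#' erfc((sigma/tau - (t - tr)/sigma) / sqrt(2))`,
#' evaluated in log space so the exponential factors never overflow. The EMG
#' preserves the Gaussian's total area `h * sigma * sqrt(2*pi)`.
#'
#' @param t Times in minutes (vectorised).
#' @param spec A [peak_spec()].
#' @return Intensities at `t`.
#' @export
peak_profile <- function(t, spec) {
  stopifnot(inherits(spec, "peak_spec"))
  s <- spec$sigma / 60   # seconds -> minutes
  dt <- t - spec$retention_time
  # tau far below sigma is numerically indistinguishable from a Gaussian but
  # loses all precision in the exp/erfc cancellation, so treat it as one
  if (spec$tau <= 1e-4 * spec$sigma) {
    return(spec$height * exp(-dt^2 / (2 * s^2)))
  }
  tau <- spec$tau / 60
  # evaluated in log space: log erfc(z) = log(2) + pnorm(-z*sqrt(2), log = TRUE)
  # stays accurate far into both tails where exp() and erfc() over/underflow
  z <- (s / tau - dt / s) / sqrt(2)
  log_erfc <- log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  amp <- spec$height * (s / tau) * sqrt(pi / 2)
  amp * exp(s^2 / (2 * tau^2) - dt / tau + log_erfc)
}

#' Specify a synthetic chromatogram
#'
#' The generated trace decomposes exactly as `I(t) = S(t) + N(t)`: the pure
#' signal `S` is a baseline (level plus linear drift) with peaks on top, and
#' `N` is Gaussian white noise from a seeded generator, the simplest
#' stationary model consistent with estimating the noise level as a baseline
#' window's standard deviation.
#'
#' @param peaks List of [peak_spec()] objects.
#' @param duration Trace length in minutes (starts at 0).
#' @param sampling_rate Sampling rate in Hz.
#' @param baseline_level Constant baseline, intensity units.
#' @param baseline_drift Linear drift, intensity units per minute.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(peaks, duration = 30, sampling_rate = 10,
                           baseline_level = 0, baseline_drift = 0,
                           noise_sd = 0, seed = NULL) {
  if (!is_number(duration) || duration <= 0) {
    abort_ssr("duration must be positive", "ssr_parameter_error")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort_ssr("noise_sd must be >= 0", "ssr_parameter_error")
  }
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(
    list(peaks = peaks, duration = duration, sampling_rate = sampling_rate,
         baseline_level = baseline_level, baseline_drift = baseline_drift,
         noise_sd = noise_sd, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic chromatogram with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list of three aligned [chromatogram()]s: `chromatogram` (the
#'   observed trace I), `signal` (the pure signal S) and `noise` (N), with
#'   `I = S + N` exactly.
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dt <- 1 / (60 * spec$sampling_rate)
  times <- seq(0, spec$duration, by = dt)
  s <- spec$baseline_level + spec$baseline_drift * times
  for (p in spec$peaks) s <- s + peak_profile(times, p)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- stats::rnorm(length(times), sd = spec$noise_sd)
  list(
    chromatogram = chromatogram(times, s + n, spec$sampling_rate),
    signal = chromatogram(times, s, spec$sampling_rate),
    noise = chromatogram(times, n, spec$sampling_rate)
  )
}

# Peak table emulating a five-dye trace: retention times near 4.5, 6.0, 10.4,
# 15.8 and 25.9 min, widths growing with retention as usual in gradient HPLC,
# moderate tailing on the later peaks, and heights placing the raw windowed
# SNR around 2-3 against unit noise -- weak enough that direct quantitation
# is unreliable.
sudan_peak_table <- function(scale = 1) {
  list(
    peak_spec(4.5,  6.0 * scale, sigma = 3.0, tau = 0),
    peak_spec(6.0,  7.0 * scale, sigma = 3.6, tau = 1.2),
    peak_spec(10.4, 5.5 * scale, sigma = 4.8, tau = 1.8),
    peak_spec(15.8, 6.5 * scale, sigma = 6.0, tau = 2.4),
    peak_spec(25.9, 5.0 * scale, sigma = 7.5, tau = 3.0)
  )
}

#' Seeded five-peak fixture emulating a weak dye chromatogram
#'
#' Generates a 0-30 min trace at 10 Hz with five peaks at 4.5, 6.0, 10.4,
#' 15.8 and 25.9 min over a flat baseline (level 10, unit white noise),
#' slices it to the 2-29 min analysis window (16,201 samples) and returns one
#' [peak_window()] per peak: signal range `tr +/- 4*sigma`, baseline range in
#' the nearest flat inter-peak region.
#'
#' @param input_snr_scale Multiplies all peak heights; 1 (default) puts the
#'   weakest peaks near the detection limit.
#' @param seed Integer seed for the noise (default 42).
#' @return List with `chromatogram` (sliced observed trace), `signal` (sliced
#'   pure signal), `windows` and the `spec` used.
#' @export
sudan_like_fixture <- function(input_snr_scale = 1, seed = 42) {
  if (!is_number(input_snr_scale) || input_snr_scale <= 0) {
    abort_ssr("input_snr_scale must be positive", "ssr_parameter_error")
  }
  peaks <- sudan_peak_table(input_snr_scale)
  spec <- synthetic_spec(peaks, duration = 30, sampling_rate = 10,
                         baseline_level = 10, baseline_drift = 0,
                         noise_sd = 1, seed = seed)
  out <- synthesize(spec)
  baselines <- list(c(2.5, 3.5), c(7.0, 8.0), c(12.0, 13.0),
                    c(18.0, 19.0), c(27.5, 28.5))
  windows <- lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    half <- 4 * p$sigma / 60
    peak_window(sprintf("peak%d", i),
                p$retention_time - half, p$retention_time + half,
                baselines[[i]][1], baselines[[i]][2])
  })
  list(
    chromatogram = slice_time_range(out$chromatogram, 2, 29),
    signal = slice_time_range(out$signal, 2, 29),
    windows = windows,
    spec = spec
  )
}

#' Relative concentration series for end-to-end calibration tests
#'
#' A seven-level dilution design (relative concentrations 1.0, 1.5, 2.0, 2.5,
#' 3.0, 4.0, 5.0) of the five-peak fixture: peak heights scale with
#' concentration, noise is redrawn per level from `seed + level`.
#'
#' @param seed Base seed (default 42).
#' @return List with `levels` (numeric vector) and `fixtures` (one
#'   [sudan_like_fixture()] result per level).
#' @export
concentration_series <- function(seed = 42) {
  levels <- c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 5.0)
  fixtures <- lapply(seq_along(levels), function(i) {
    sudan_like_fixture(input_snr_scale = levels[i], seed = seed + i)
  })
  list(levels = levels, fixtures = fixtures)
}
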