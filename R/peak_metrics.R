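#' Sample standard deviation of an intensity window
#'
#' Uses the n-1 denominator, the usual convention for noise estimation on a
#' finite window.
#'
#' @param values Numeric vector, length >= 2.
#' @return The sample standard deviation.
#' @export
sample_sd <- function(values) {
  if (length(values) < 2L) {
    abort_ssr("need at least 2 values for a standard deviation", "ssr_data_error")
  }
  stats::sd(values)
}

#' Signal-to-noise ratio of one peak
#'
#' The SNR of a peak is the ratio of the sample standard deviation of the
#' trace over the peak's signal range to that over its baseline range. Both
#' windows scale together under vertical scaling of the trace, so the ratio is
#' gain-invariant.
#'
#' @param trace A [chromatogram()] or enhanced trace.
#' @param window A [peak_window()].
#' @return SNR, dimensionless.
#' @export
snr_of_peak <- function(trace, window) {
  sig <- window_indices(trace, window$signal_start, window$signal_end,
                        sprintf("peak '%s' signal range", window$peak_id))
  base <- window_indices(trace, window$baseline_start, window$baseline_end,
                         sprintf("peak '%s' baseline range", window$peak_id))
  sd_noise <- sample_sd(trace$intensities[base])
  if (sd_noise == 0) {
    abort_ssr(sprintf("peak '%s': baseline range has zero standard deviation",
                      window$peak_id), "ssr_degenerate_error")
  }
  sample_sd(trace$intensities[sig]) / sd_noise
}

#' Locate the apex of a peak within its signal range
#'
#' Returns the index (into the full trace) of the maximum intensity inside the
#' signal range, taking the earliest sample on ties. The apex must be interior
#' to the range, otherwise the left/right split is undefined.
#'
#' @param trace A [chromatogram()] or enhanced trace.
#' @param window A [peak_window()].
#' @return Integer sample index of the apex.
#' @export
apex_split <- function(trace, window) {
  sig <- window_indices(trace, window$signal_start, window$signal_end,
                        sprintf("peak '%s' signal range", window$peak_id))
  apex <- sig[which.max(trace$intensities[sig])]
  if (apex == sig[1L] || apex == sig[length(sig)]) {
    abort_ssr(sprintf("peak '%s': apex falls on the signal-range boundary",
                      window$peak_id), "ssr_degenerate_error")
  }
  apex
}

# Chord baseline correction over a set of indices: subtract the straight line
# joining the first and last samples of the range. Robust to the DC offset
# that the 1/b gain of the enhancement introduces.
chord_corrected <- function(trace, idx) {
  t <- trace$times[idx]
  y <- trace$intensities[idx]
  n <- length(idx)
  y - (y[1L] + (y[n] - y[1L]) * (t - t[1L]) / (t[n] - t[1L]))
}

#' Peak asymmetry score
#'
#' After subtracting the chord joining the signal-range endpoints, the peak is
#' split at its apex; `LA` and `RA` are the trapezoidal areas of the left and
#' right halves (the apex sample bounds both). The score `|LA/RA - 1|` is 0
#' for a perfectly symmetric peak and grows with fronting or tailing.
#'
#' @param trace A [chromatogram()] or enhanced trace.
#' @param window A [peak_window()].
#' @return Asymmetry score >= 0.
#' @export
syn_of_peak <- function(trace, window) {
  parts <- peak_areas_split(trace, window)
  if (parts$ra <= 0) {
    abort_ssr(sprintf("peak '%s': nonpositive right-side area", window$peak_id),
              "ssr_degenerate_error")
  }
  abs(parts$la / parts$ra - 1)
}

# LA/RA split used by both the asymmetry score and quantitation.
peak_areas_split <- function(trace, window) {
  sig <- window_indices(trace, window$signal_start, window$signal_end,
                        sprintf("peak '%s' signal range", window$peak_id))
  apex <- apex_split(trace, window)
  y <- chord_corrected(trace, sig)
  t <- trace$times[sig]
  k <- match(apex, sig)
  list(
    apex_index = apex,
    la = pracma::trapz(t[1:k], y[1:k]),
    ra = pracma::trapz(t[k:length(sig)], y[k:length(sig)])
  )
}

#' Per-peak metric table
#'
#' Computes SNR, asymmetry, apex position and areas for every window on one
#' trace; suitable for export as a delimited table.
#'
#' @param trace A [chromatogram()] or enhanced trace.
#' @param windows List of [peak_window()] objects.
#' @return A data frame with one row per peak: `peak_id`, `snr`, `syn`,
#'   `apex_time`, `left_area`, `right_area`, `area`.
#' @export
peak_metrics_table <- function(trace, windows) {
  rows <- lapply(windows, function(w) {
    parts <- peak_areas_split(trace, w)
    data.frame(
      peak_id = w$peak_id,
      snr = snr_of_peak(trace, w),
      syn = abs(parts$la / parts$ra - 1),
      apex_time = trace$times[parts$apex_index],
      left_area = parts$la,
      right_area = parts$ra,
      area = parts$la + parts$ra,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Two-objective value of a candidate b
#'
#' Enhances the chromatogram with [rk4_enhance()] at the candidate `b` and
#' aggregates the per-peak metrics into the two minimisation objectives:
#' `f1 = -sum_i SNR_i / SNR_i^max` (maximise normalised SNR) and
#' `f2 = sum_i SYN_i / SYN_i^max` (minimise normalised asymmetry).
#'
#' @param b Candidate well steepness in `(0, 1]`.
#' @param chrom Input [chromatogram()].
#' @param windows List of [peak_window()] objects.
#' @param normalizers Per-peak maxima from [compute_normalizers()].
#' @param x0,subtract_median Passed to [rk4_enhance()].
#' @param degenerate What to do when a peak's metrics are undefined at this
#'   `b` (apex on a window boundary, nonpositive right area — typical of very
#'   small `b`, where the output is close to a running integral of the input):
#'   `"error"` propagates the condition with the peak id attached;
#'   `"penalize"` scores that peak at the worst admissible values (SNR 0,
#'   asymmetry at its normaliser), which is what the optimizer uses so that an
#'   unusable candidate is dominated rather than fatal.
#' @return List with `f1`, `f2`, `n` (number of peaks) and `per_peak`
#'   (data frame of raw SNR/SYN values).
#' @export
objective_vector <- function(b, chrom, windows, normalizers,
                             x0 = NULL, subtract_median = FALSE,
                             degenerate = c("error", "penalize")) {
  check_b(b)
  degenerate <- match.arg(degenerate)
  stopifnot(is.list(normalizers),
            length(normalizers$snr_max) == length(windows),
            length(normalizers$syn_max) == length(windows))
  if (any(normalizers$snr_max <= 0) || any(normalizers$syn_max <= 0)) {
    abort_ssr("normalizers must be positive", "ssr_parameter_error")
  }
  enhanced <- rk4_enhance(chrom, b, x0 = x0, subtract_median = subtract_median)
  snr <- numeric(length(windows))
  syn <- numeric(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    res <- tryCatch(
      list(snr = snr_of_peak(enhanced, w), syn = syn_of_peak(enhanced, w)),
      ssr_error = function(e) {
        if (degenerate == "penalize") {
          list(snr = 0, syn = normalizers$syn_max[[i]])
        } else {
          abort_ssr(sprintf("peak '%s': %s", w$peak_id, conditionMessage(e)),
                    class(e)[1L])
        }
      }
    )
    snr[i] <- res$snr
    syn[i] <- res$syn
  }
  list(
    f1 = -sum(snr / normalizers$snr_max),
    f2 = sum(syn / normalizers$syn_max),
    n = length(windows),
    per_peak = data.frame(
      peak_id = vapply(windows, `[[`, "", "peak_id"),
      snr = snr, syn = syn, stringsAsFactors = FALSE
    )
  )
}

#' Default pre-scan grid for the objective normalizers
#'
#' A geometric grid of `n` values of b spanning `[2^-20, 1]`, covering the
#' full dynamic range of the 20-bit encoding.
#'
#' @param n Number of grid points (default 64).
#' @return Numeric vector of b values in `(0, 1]`.
#' @export
default_b_grid <- function(n = 64) {
  2^seq(-20, 0, length.out = n)
}

#' Pre-scan per-peak maxima used to normalise the objectives
#'
#' Evaluates SNR and asymmetry for every peak over a grid of b values and
#' records the per-peak maxima. The optimizer divides each peak's metrics by
#' these, so every peak contributes on a comparable scale regardless of its
#' height. The maxima are computed once, before the search, keeping the
#' objectives stationary across generations. A zero maximum (e.g. an exactly
#' symmetric peak at every grid b) is replaced by 1, disabling normalisation
#' for that term.
#'
#' @param chrom Input [chromatogram()].
#' @param windows List of [peak_window()] objects.
#' @param b_grid Grid of b values in `(0, 1]`, length >= 2
#'   (default [default_b_grid()]).
#' @param x0,subtract_median Passed to [rk4_enhance()].
#' @return List with `snr_max` and `syn_max` (named per-peak vectors) and the
#'   grid used.
#' @export
compute_normalizers <- function(chrom, windows, b_grid = default_b_grid(),
                                x0 = NULL, subtract_median = FALSE) {
  if (length(b_grid) < 2L) {
    abort_ssr("b_grid needs at least 2 values", "ssr_parameter_error")
  }
  for (b in b_grid) check_b(b)
  ids <- vapply(windows, `[[`, "", "peak_id")
  snr_max <- stats::setNames(numeric(length(windows)), ids)
  syn_max <- stats::setNames(numeric(length(windows)), ids)
  for (b in b_grid) {
    enhanced <- rk4_enhance(chrom, b, x0 = x0, subtract_median = subtract_median)
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      # grid points where a peak's metrics are undefined contribute no maximum
      m <- tryCatch(
        c(snr_of_peak(enhanced, w), syn_of_peak(enhanced, w)),
        ssr_error = function(e) c(0, 0)
      )
      snr_max[i] <- max(snr_max[i], m[1L])
      syn_max[i] <- max(syn_max[i], m[2L])
    }
  }
  snr_max[snr_max == 0] <- 1
  syn_max[syn_max == 0] <- 1
  list(snr_max = snr_max, syn_max = syn_max, b_grid = b_grid)
}
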