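#' Define a peak window
#'
#' A peak window names a chromatographic peak and gives two disjoint time
#' intervals on the trace: the signal range containing the peak, and a nearby
#' flat baseline range used to estimate the noise level. Retention times are
#' assumed known (as in targeted trace analysis); no peak detection is done.
#'
#' @param peak_id Character label for the peak.
#' @param signal_start,signal_end Signal range in minutes, `start < end`.
#' @param baseline_start,baseline_end Baseline range in minutes, `start < end`,
#'   disjoint from the signal range.
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(peak_id, signal_start, signal_end,
                        baseline_start, baseline_end) {
  for (v in list(signal_start, signal_end, baseline_start, baseline_end)) {
    if (!is_number(v)) abort_ssr("window bounds must be finite numbers", "ssr_format_error")
  }
  if (signal_start >= signal_end) {
    abort_ssr("signal_start must be < signal_end", "ssr_format_error")
  }
  if (baseline_start >= baseline_end) {
    abort_ssr("baseline_start must be < baseline_end", "ssr_format_error")
  }
  if (signal_start < baseline_end && baseline_start < signal_end) {
    abort_ssr(sprintf("peak '%s': signal and baseline ranges overlap", peak_id),
              "ssr_format_error")
  }
  structure(
    list(
      peak_id = as.character(peak_id),
      signal_start = signal_start, signal_end = signal_end,
      baseline_start = baseline_start, baseline_end = baseline_end
    ),
    class = "peak_window"
  )
}

#' @export
print.peak_window <- function(x, ...) {
  cat(sprintf("<peak_window> %s: signal [%g, %g] min, baseline [%g, %g] min\n",
              x$peak_id, x$signal_start, x$signal_end,
              x$baseline_start, x$baseline_end))
  invisible(x)
}

# Sample indices of a [start, end] minute interval, with the same closed
# interval convention and tolerance as slice_time_range(). Each metric window
# must hold >= 3 samples at the trace's rate.
window_indices <- function(chrom, start, end, what = "window") {
  tol <- 1e-6 / (60 * chrom$sampling_rate)
  idx <- which(chrom$times >= start - tol & chrom$times <= end + tol)
  if (length(idx) < 3L) {
    abort_ssr(
      sprintf("%s [%g, %g] min holds %d samples; need >= 3",
              what, start, end, length(idx)),
      "ssr_data_error"
    )
  }
  idx
}

#' Read peak windows from a YAML config
#'
#' The file holds a top-level `windows:` list, each entry with `peak_id`,
#' `signal: [start, end]` and `baseline: [start, end]` in minutes.
#'
#' @param path Path to the YAML file.
#' @return List of [peak_window()] objects.
#' @export
read_peak_windows <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_ssr(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
              "ssr_parse_error")
  })
  entries <- cfg$windows
  if (is.null(entries) || length(entries) == 0L) {
    abort_ssr(sprintf("'%s' defines no windows", path), "ssr_parse_error")
  }
  lapply(entries, function(w) {
    if (is.null(w$peak_id) || length(w$signal) != 2L || length(w$baseline) != 2L) {
      abort_ssr(sprintf("'%s': each window needs peak_id, signal [a, b], baseline [a, b]",
                        path), "ssr_parse_error")
    }
    peak_window(w$peak_id, w$signal[[1]], w$signal[[2]],
                w$baseline[[1]], w$baseline[[2]])
  })
}

#' Write peak windows to a YAML config
#'
#' @param windows List of [peak_window()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peak_windows <- function(windows, path) {
  entries <- lapply(windows, function(w) {
    list(
      peak_id = w$peak_id,
      signal = c(w$signal_start, w$signal_end),
      baseline = c(w$baseline_start, w$baseline_end)
    )
  })
  yaml::write_yaml(list(windows = entries), path)
  invisible(path)
}
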