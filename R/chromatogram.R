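#' Construct a chromatogram
#'
#' A chromatogram is a uniformly sampled detector trace: retention times in
#' minutes and intensities in arbitrary detector units. The sampling rate is
#' stored in Hz (the dye traces this package emulates were acquired at 10 Hz,
#' i.e. 1/600 min between samples).
#'
#' @param times Numeric vector of retention times in minutes, strictly
#'   increasing with uniform spacing.
#' @param intensities Numeric vector of detector responses, same length as
#'   `times`.
#' @param sampling_rate Sampling rate in Hz, or `NULL` to infer it from the
#'   median time spacing.
#' @return An object of class `chromatogram`: a list with elements `times`,
#'   `intensities` and `sampling_rate`.
#' @examples
#' chrom <- chromatogram(seq(0, 1, by = 1/600), rnorm(601), sampling_rate = 10)
#' chrom
#' @export
chromatogram <- function(times, intensities, sampling_rate = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    abort_ssr("times and intensities must have equal length", "ssr_format_error")
  }
  if (length(times) < 2L) {
    abort_ssr("a chromatogram needs at least 2 samples", "ssr_format_error")
  }
  if (!all(is.finite(times)) || !all(is.finite(intensities))) {
    abort_ssr("non-finite values in chromatogram", "ssr_format_error")
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    abort_ssr("times must be strictly increasing", "ssr_format_error")
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / (60 * stats::median(dt))
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    abort_ssr("sampling_rate must be a positive number", "ssr_format_error")
  }
  dt_expected <- 1 / (60 * sampling_rate)
  if (any(abs(dt - dt_expected) > 1e-6 * dt_expected)) {
    abort_ssr(
      sprintf(
        "non-uniform sampling: spacing deviates from %.9g min beyond 1e-6 relative",
        dt_expected
      ),
      "ssr_format_error"
    )
  }
  structure(
    list(times = times, intensities = intensities, sampling_rate = sampling_rate),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %d samples, %.4g-%.4g min at %.4g Hz\n",
    length(x$times), x$times[1], x$times[length(x$times)], x$sampling_rate
  ))
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$times)

#' Read a chromatogram from delimited text
#'
#' Reads a two-column text file (comma- or tab-separated) of retention time in
#' minutes and detector intensity. An optional single header line is detected
#' automatically (first line with a non-numeric field), matching the CSV
#' exports of common chromatography data systems.
#'
#' @param path Path to the file.
#' @param sampling_rate Sampling rate in Hz, or `NULL` (default) to infer it
#'   from the median spacing of the time column.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) {
    abort_ssr(sprintf("cannot read '%s': no such file", path), "ssr_parse_error")
  }
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) {
    abort_ssr(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
              "ssr_parse_error")
  })
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_ssr(sprintf("'%s' contains no data", path), "ssr_parse_error")
  }
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "\t"
  split_row <- function(line) trimws(strsplit(line, sep, fixed = TRUE)[[1]])
  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  has_header <- anyNA(first)
  data_lines <- if (has_header) lines[-1L] else lines
  if (length(data_lines) == 0L) {
    abort_ssr(sprintf("'%s' has a header but no data rows", path), "ssr_parse_error")
  }
  fields <- lapply(data_lines, split_row)
  ncol <- lengths(fields)
  if (any(ncol < 2L)) {
    abort_ssr(sprintf("'%s': every data row needs two columns", path), "ssr_parse_error")
  }
  times <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  intens <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(times) || anyNA(intens)) {
    bad <- which(is.na(times) | is.na(intens))[1L]
    abort_ssr(sprintf("'%s': non-numeric value in data row %d", path, bad),
              "ssr_parse_error")
  }
  if (length(times) < 2L) {
    abort_ssr(sprintf("'%s': need at least 2 data rows", path), "ssr_parse_error")
  }
  chromatogram(times, intens, sampling_rate = sampling_rate)
}

#' Write a chromatogram to delimited text
#'
#' Writes a two-column CSV (`time_min,intensity`) with enough digits that
#' [read_chromatogram()] reproduces the trace to better than 1e-9 relative.
#'
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  out <- c(
    "time_min,intensity",
    sprintf("%.15g,%.15g", chrom$times, chrom$intensities)
  )
  tryCatch(writeLines(out, path), error = function(e) {
    abort_ssr(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
              "ssr_io_error")
  })
  invisible(path)
}

#' Extract a closed time interval from a chromatogram
#'
#' Keeps all samples with `t0 <= t <= t1` (both endpoints included, so an
#' interval of w minutes at rate f Hz yields `60*w*f + 1` samples). Used to
#' restrict the enhancement input to the analysis window and exclude foreign
#' early/late-eluting components.
#'
#' @param chrom A [chromatogram()].
#' @param t0,t1 Interval bounds in minutes, `t0 < t1`, both inside the trace.
#' @return A [chromatogram()] with the same sampling rate.
#' @export
slice_time_range <- function(chrom, t0, t1) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!is_number(t0) || !is_number(t1) || t0 >= t1) {
    abort_ssr("need t0 < t1", "ssr_range_error")
  }
  tol <- 1e-6 / (60 * chrom$sampling_rate)
  tmin <- chrom$times[1L]
  tmax <- chrom$times[length(chrom$times)]
  if (t0 < tmin - tol || t1 > tmax + tol) {
    abort_ssr(
      sprintf("[%g, %g] outside trace span [%g, %g] min", t0, t1, tmin, tmax),
      "ssr_range_error"
    )
  }
  keep <- chrom$times >= t0 - tol & chrom$times <= t1 + tol
  chromatogram(chrom$times[keep], chrom$intensities[keep],
               sampling_rate = chrom$sampling_rate)
}
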