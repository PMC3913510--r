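#' Peak area on a (possibly enhanced) trace
#'
#' Trapezoidal area of the signal range after chord baseline correction (the
#' straight line joining the signal-range endpoint samples is subtracted, the
#' same convention as [syn_of_peak()]). When the apex is interior the area
#' equals `LA + RA`. Time is in minutes, so areas are intensity-minutes.
#'
#' @param trace A [chromatogram()] or enhanced trace.
#' @param window A [peak_window()].
#' @return Peak area.
#' @export
peak_area <- function(trace, window) {
  sig <- window_indices(trace, window$signal_start, window$signal_end,
                        sprintf("peak '%s' signal range", window$peak_id))
  pracma::trapz(trace$times[sig], chord_corrected(trace, sig))
}

#' Fit an ordinary least-squares calibration line
#'
#' Fits `A = slope * c + intercept` by OLS (via [stats::lm()]) and reports the
#' conventions of chromatographic method validation: the ± values are the
#' standard errors of slope and intercept, `r` is the Pearson correlation of
#' concentration and area, and the residual SD uses n-2 degrees of freedom.
#'
#' @param conc Concentrations (e.g. ng/mL).
#' @param areas Peak areas at those concentrations.
#' @return An object of class `calibration_fit` with fields `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r`, `resid_sd`, `n`.
#' @examples
#' fit <- fit_calibration_line(c(1, 2, 3, 4, 5), c(2.9, 5.1, 7.0, 9.2, 10.9))
#' fit
#' @export
fit_calibration_line <- function(conc, areas) {
  conc <- as.numeric(conc)
  areas <- as.numeric(areas)
  if (length(conc) != length(areas) || length(conc) < 3L) {
    abort_ssr("need >= 3 (concentration, area) pairs of equal length",
              "ssr_data_error")
  }
  if (!all(is.finite(conc)) || !all(is.finite(areas))) {
    abort_ssr("non-finite calibration values", "ssr_data_error")
  }
  if (stats::var(conc) == 0) {
    abort_ssr("concentrations are all equal", "ssr_data_error")
  }
  fit <- stats::lm(areas ~ conc)
  s <- summary(fit)$coefficients
  structure(
    list(
      slope = unname(s["conc", "Estimate"]),
      slope_se = unname(s["conc", "Std. Error"]),
      intercept = unname(s["(Intercept)", "Estimate"]),
      intercept_se = unname(s["(Intercept)", "Std. Error"]),
      r = stats::cor(conc, areas),
      resid_sd = summary(fit)$sigma,
      n = length(conc)
    ),
    class = "calibration_fit"
  )
}

#' Format a calibration fit in the conventional report style
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return A string like
#'   `"A = (156.1 ± 6.999)c + (1231 ± 303.6), r = 0.9950, SD = 348.1"`,
#'   with 4 significant figures and r to 4 decimals.
#' @export
format.calibration_fit <- function(x, ...) {
  int_sign <- if (x$intercept < 0) "-" else "+"
  sprintf(
    "A = (%s ± %s)c %s (%s ± %s), r = %.4f, SD = %s",
    signif(x$slope, 4), signif(x$slope_se, 4),
    int_sign, signif(abs(x$intercept), 4), signif(x$intercept_se, 4),
    x$r, signif(x$resid_sd, 4)
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", format(x), sprintf("(n = %d)\n", x$n))
  invisible(x)
}

#' Fit calibration lines for several analytes
#'
#' @param series A data frame with columns `label`, `concentration`, `area`
#'   (one row per calibration point), or a named list of
#'   `list(conc = , areas = )` entries.
#' @return A data frame with one row per label: the fit statistics, the
#'   formatted equation, and an `error` column (`NA` on success; series that
#'   fail to fit report the message there and `NA` statistics).
#' @export
calibration_table <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("label", "concentration", "area") %in% names(series))) {
      abort_ssr("series data frame needs columns label, concentration, area",
                "ssr_data_error")
    }
    series <- lapply(split(series, factor(series$label, levels = unique(series$label))),
                     function(d) list(conc = d$concentration, areas = d$area))
  }
  rows <- lapply(names(series), function(label) {
    res <- tryCatch(
      fit_calibration_line(series[[label]]$conc, series[[label]]$areas),
      ssr_error = function(e) e
    )
    if (inherits(res, "condition")) {
      data.frame(label = label, slope = NA_real_, slope_se = NA_real_,
                 intercept = NA_real_, intercept_se = NA_real_, r = NA_real_,
                 resid_sd = NA_real_, n = NA_integer_,
                 equation = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(label = label, slope = res$slope, slope_se = res$slope_se,
                 intercept = res$intercept, intercept_se = res$intercept_se,
                 r = res$r, resid_sd = res$resid_sd, n = res$n,
                 equation = format(res), error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0L) {
    return(data.frame(label = character(0), slope = numeric(0),
                      slope_se = numeric(0), intercept = numeric(0),
                      intercept_se = numeric(0), r = numeric(0),
                      resid_sd = numeric(0), n = integer(0),
                      equation = character(0), error = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Published dye calibration series
#'
#' The seven-level calibration table of five azo dyes (Para Red and Sudan
#' I-IV) determined by reversed-phase HPLC with stochastic-resonance peak
#' enhancement: concentration in ng/mL against enhanced peak area. Bundled as
#' plain CSV; used to validate the regression statistics end to end.
#'
#' @return A data frame with columns `label`, `concentration`, `area`.
#' @export
sudan_calibration <- function() {
  path <- system.file("extdata", "sudan_calibration.csv", package = "ssrtrace",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
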