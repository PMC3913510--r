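# Independent oracles, written without reference to the package internals.

# Literal k1..k4 Runge-Kutta loop for dx/dt = -b*x + u, advancing one sample
# per step with step size h. The half-step input is interpolated from the
# surrounding samples (cubic in the interior, quadratic at the ends).
rk4_loop_oracle <- function(u, b, x0 = 0, h = 1) {
  n <- length(u)
  x <- numeric(n)
  x[1] <- x0
  f <- function(x, u) -b * x + u
  for (i in seq_len(n - 1)) {
    um <- if (n == 2) {
      (u[1] + u[2]) / 2
    } else if (i == 1) {
      (3 * u[1] + 6 * u[2] - u[3]) / 8
    } else if (i == n - 1) {
      (3 * u[n] + 6 * u[n - 1] - u[n - 2]) / 8
    } else {
      (-u[i - 1] + 9 * u[i] + 9 * u[i + 1] - u[i + 2]) / 16
    }
    k1 <- f(x[i], u[i])
    k2 <- f(x[i] + h * k1 / 2, um)
    k3 <- f(x[i] + h * k2 / 2, um)
    k4 <- f(x[i] + h * k3, u[i + 1])
    x[i + 1] <- x[i] + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Closed-form OLS statistics for A = slope*c + intercept.
ols_oracle <- function(conc, area) {
  n <- length(conc)
  cbar <- mean(conc)
  abar <- mean(area)
  sxx <- sum((conc - cbar)^2)
  slope <- sum((conc - cbar) * (area - abar)) / sxx
  intercept <- abar - slope * cbar
  rss <- sum((area - slope * conc - intercept)^2)
  resid_sd <- sqrt(rss / (n - 2))
  list(
    slope = slope,
    intercept = intercept,
    slope_se = resid_sd / sqrt(sxx),
    intercept_se = resid_sd * sqrt(1 / n + cbar^2 / sxx),
    r = sum((conc - cbar) * (area - abar)) /
      sqrt(sxx * sum((area - abar)^2)),
    resid_sd = resid_sd
  )
}

# Published regression statistics for the five-dye calibration table, as
# printed (4 significant figures; r to 4 decimals).
dye_expected_fits <- list(
  para_red  = list(slope = 156.1, slope_se = 6.999, intercept = 1231,
                   intercept_se = 303.6, r = 0.9950, resid_sd = 348.1),
  sudan_i   = list(slope = 125.5, slope_se = 3.575, intercept = 1599,
                   intercept_se = 219.6, r = 0.9980, resid_sd = 251.9),
  sudan_ii  = list(slope = 96.20, slope_se = 2.178, intercept = 3150,
                   intercept_se = 329.2, r = 0.9987, resid_sd = 377.6),
  sudan_iii = list(slope = 161.1, slope_se = 5.481, intercept = -307.1,
                   intercept_se = 815.5, r = 0.9971, resid_sd = 935.2),
  sudan_iv  = list(slope = 61.77, slope_se = 2.273, intercept = 1171,
                   intercept_se = 829.8, r = 0.9966, resid_sd = 951.6)
)

# A small two-peak trace that makes objective evaluations cheap enough for
# exercising the genetic algorithm machinery in unit tests.
small_ga_fixture <- function(seed = 7) {
  peaks <- list(
    peak_spec(1.0, 5, sigma = 5, tau = 0),
    peak_spec(2.5, 6, sigma = 6, tau = 2)
  )
  spec <- synthetic_spec(peaks, duration = 4, sampling_rate = 2,
                         baseline_level = 5, noise_sd = 1, seed = seed)
  out <- synthesize(spec)
  windows <- list(
    peak_window("p1", 1.0 - 4 * 5 / 60, 1.0 + 4 * 5 / 60, 3.2, 3.9),
    peak_window("p2", 2.5 - 4 * 6 / 60, 2.5 + 4 * 6 / 60, 0.1, 0.6)
  )
  list(chromatogram = out$chromatogram, windows = windows)
}
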