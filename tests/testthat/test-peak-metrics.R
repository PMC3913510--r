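test_that("sample_sd uses the n-1 denominator", {
  expect_equal(sample_sd(c(0, 2, 4, 2, 0)), sqrt(11.2 / 4))  # 1.67332...
  expect_equal(sample_sd(rep(3, 10)), 0)
  expect_error(sample_sd(5), class = "ssr_data_error")
})

test_that("peak SNR is the ratio of signal to baseline window SDs", {
  trace <- chromatogram(0:9, c(1, 0, -1, 0, 0, 0, 2, 4, 2, 0))
  w <- peak_window("p", 5, 9, 0, 4)
  expect_equal(snr_of_peak(trace, w), sqrt(11.2 / 4) / sqrt(0.5),
               tolerance = 1e-6)  # 1.67332 / 0.70711 = 2.36644

  # identical windows drawn from one sequence give SNR 1
  rep_trace <- chromatogram(0:9, rep(c(0, 1, 3, 1, 0), 2))
  expect_equal(snr_of_peak(rep_trace, w), 1)

  flat <- chromatogram(0:9, c(rep(2, 5), 0, 2, 4, 2, 0))
  expect_error(snr_of_peak(flat, w), class = "ssr_degenerate_error")
})

test_that("the apex is the earliest maximum and must be interior", {
  w <- peak_window("p", 0, 4, 6, 10)
  expect_equal(apex_split(chromatogram(0:4, c(0, 1, 2, 1, 0)), w), 3L)
  expect_equal(apex_split(chromatogram(0:4, c(0, 2, 2, 1, 0)), w), 2L)
  expect_error(apex_split(chromatogram(0:4, c(3, 2, 1, 0, 0)), w),
               class = "ssr_degenerate_error")
  expect_error(apex_split(chromatogram(0:4, c(0, 1, 2, 3, 4)), w),
               class = "ssr_degenerate_error")
})

test_that("asymmetry is the areal left/right imbalance about the apex", {
  w <- peak_window("p", 0, 4, 6, 10)
  expect_equal(syn_of_peak(chromatogram(0:4, c(0, 1, 2, 1, 0)), w), 0)
  expect_equal(syn_of_peak(chromatogram(0:4, c(0, 2, 4, 1, 0)), w), 1 / 3,
               tolerance = 1e-9)  # LA = 4, RA = 3
  # LA = 2*RA gives score 1: trapezoids 1+3=4 left, 2+0=2 right... construct
  trace <- chromatogram(0:4, c(0, 2, 4, 0, 0))
  expect_equal(syn_of_peak(trace, w), 1, tolerance = 1e-9)  # LA = 4, RA = 2
})

test_that("metrics are invariant under vertical scaling and offsets", {
  fix <- small_ga_fixture()
  w <- fix$windows[[1]]
  tr <- fix$chromatogram
  scaled <- chromatogram(tr$times, 7.5 * tr$intensities, tr$sampling_rate)
  shifted <- chromatogram(tr$times, tr$intensities + 123, tr$sampling_rate)
  expect_equal(snr_of_peak(scaled, w), snr_of_peak(tr, w), tolerance = 1e-12)
  expect_equal(syn_of_peak(scaled, w), syn_of_peak(tr, w), tolerance = 1e-12)
  # chord correction makes the asymmetry offset-invariant too
  expect_equal(syn_of_peak(shifted, w), syn_of_peak(tr, w), tolerance = 1e-9)
})

test_that("objective vector normalises and aggregates per-peak metrics", {
  fix <- small_ga_fixture()
  b <- 0.05
  enh <- rk4_enhance(fix$chromatogram, b)
  snr <- vapply(fix$windows, function(w) snr_of_peak(enh, w), numeric(1))
  syn <- vapply(fix$windows, function(w) syn_of_peak(enh, w), numeric(1))

  # normalisers equal to the metrics at b: normalisation identity (-n, n)
  ident <- list(snr_max = snr, syn_max = syn)
  obj <- objective_vector(b, fix$chromatogram, fix$windows, ident)
  expect_equal(obj$f1, -2, tolerance = 1e-12)
  expect_equal(obj$f2, 2, tolerance = 1e-12)

  # normalisers chosen so the ratios are {0.5, 0.25} and {0.1, 0.3}
  tuned <- list(snr_max = snr / c(0.5, 0.25), syn_max = syn / c(0.1, 0.3))
  obj2 <- objective_vector(b, fix$chromatogram, fix$windows, tuned)
  expect_equal(obj2$f1, -0.75, tolerance = 1e-12)
  expect_equal(obj2$f2, 0.4, tolerance = 1e-12)

  expect_error(objective_vector(0, fix$chromatogram, fix$windows, ident),
               class = "ssr_parameter_error")
  expect_error(
    objective_vector(0.1, fix$chromatogram, fix$windows,
                     list(snr_max = c(0, 1), syn_max = c(1, 1))),
    class = "ssr_parameter_error"
  )
})

test_that("normalizers are grid maxima and bound the normalised metrics", {
  fix <- small_ga_fixture()
  # degenerate grid of one repeated b: maxima equal that b's metrics
  enh <- rk4_enhance(fix$chromatogram, 0.05)
  nm <- compute_normalizers(fix$chromatogram, fix$windows, c(0.05, 0.05))
  expect_equal(unname(nm$snr_max),
               vapply(fix$windows, function(w) snr_of_peak(enh, w), numeric(1)))
  expect_equal(unname(nm$syn_max),
               vapply(fix$windows, function(w) syn_of_peak(enh, w), numeric(1)))

  # on a real grid every normalised metric stays within [0, 1]
  grid <- default_b_grid(16)
  nm <- compute_normalizers(fix$chromatogram, fix$windows, grid)
  for (b in grid) {
    obj <- objective_vector(b, fix$chromatogram, fix$windows, nm,
                            degenerate = "penalize")
    expect_true(all(obj$per_peak$snr / nm$snr_max <= 1 + 1e-12))
    expect_true(all(obj$per_peak$syn / nm$syn_max <= 1 + 1e-12))
    expect_gte(obj$f1, -obj$n)
    expect_lte(obj$f1, 0)
    expect_gte(obj$f2, 0)
  }
})

test_that("per-peak failures carry the peak id", {
  tr <- chromatogram(0:9, c(1, 0, -1, 0, 0, 0, 1, 2, 3, 4))  # apex at edge
  w <- peak_window("rising_peak", 5, 9, 0, 4)
  nm <- list(snr_max = 1, syn_max = 1)
  err <- tryCatch(
    objective_vector(0.9, tr, list(w), nm),
    ssr_error = function(e) e
  )
  expect_match(conditionMessage(err), "rising_peak")
})
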