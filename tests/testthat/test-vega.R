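test_that("chromosomes decode onto (0, 1] with 2^-L resolution", {
  expect_equal(decode_bits(rep(1, 20)), 1)
  expect_equal(decode_bits(rep(0, 20)), 2^-20)
  bits_0.5 <- c(0, rep(1, 19))  # k = 524287
  expect_equal(decode_bits(bits_0.5), 0.5)
  expect_error(decode_bits(rep(1, 19), L = 20), class = "ssr_encoding_error")
  expect_error(decode_bits(c(rep(0, 19), 2)), class = "ssr_encoding_error")

  # every possible 8-bit code lands strictly inside (0, 1]
  b <- vapply(0:255, function(k) {
    decode_bits(as.integer(intToBits(k))[8:1])
  }, numeric(1))
  expect_true(all(b > 0 & b <= 1))
  expect_equal(sort(b), (1:256) / 256)
})

test_that("roulette selection follows the worst-minus-value weights", {
  set.seed(123)
  # all equal: uniform sampling
  idx <- proportional_select(rep(2.5, 4), 10000)
  freq <- tabulate(idx, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))

  # hand-computed weights: z = (0, 2) -> delta = 0.02, w = (2.02, 0.02)
  idx <- proportional_select(c(0, 2), 10000)
  p1 <- 2.02 / 2.04
  expect_lt(abs(mean(idx == 1) - p1), 0.02)

  # three-point block, weights (3.03, 1.03, 0.03)/4.09
  idx <- proportional_select(c(0, 2, 3), 20000)
  freq <- tabulate(idx, 3) / 20000
  expect_true(all(abs(freq - c(3.03, 1.03, 0.03) / 4.09) < 0.02))

  expect_identical(proportional_select(c(1, 2), 0), integer(0))
  expect_error(proportional_select(numeric(0), 1), class = "ssr_data_error")
})

test_that("a generation conserves size, seeds reproduce bit-identically", {
  fix <- small_ga_fixture()
  cfg <- ga_config(pop_size = 12, max_generations = 1, bits = 10, seed = 1)
  nm <- compute_normalizers(fix$chromatogram, fix$windows, default_b_grid(8))

  set.seed(1)
  pop <- ssrtrace:::evaluate_population(
    ssrtrace:::random_population(cfg),
    ssrtrace:::make_evaluator(fix$chromatogram, fix$windows, nm, 0, FALSE),
    new.env(parent = emptyenv())
  )
  set.seed(99)
  nxt1 <- vega_generation(pop, fix$chromatogram, fix$windows, nm, cfg)
  set.seed(99)
  nxt2 <- vega_generation(pop, fix$chromatogram, fix$windows, nm, cfg)
  expect_identical(nxt1$bits, nxt2$bits)
  expect_identical(nxt1$f1, nxt2$f1)
  expect_equal(nrow(nxt1$bits), 12L)
  expect_equal(nxt1$t, pop$t + 1L)
  expect_true(all(nxt1$b > 0 & nxt1$b <= 1))

  unevaluated <- ssrtrace:::random_population(cfg)
  expect_error(
    vega_generation(unevaluated, fix$chromatogram, fix$windows, nm, cfg),
    class = "ssr_state_error"
  )
})

test_that("without crossover or mutation breeding is pure resampling", {
  fix <- small_ga_fixture()
  cfg <- ga_config(pop_size = 12, bits = 10, crossover_prob = 0,
                   mutation_prob = 0, generation_gap = 1, seed = 2)
  nm <- compute_normalizers(fix$chromatogram, fix$windows, default_b_grid(8))
  set.seed(2)
  pop <- ssrtrace:::evaluate_population(
    ssrtrace:::random_population(cfg),
    ssrtrace:::make_evaluator(fix$chromatogram, fix$windows, nm, 0, FALSE),
    new.env(parent = emptyenv())
  )
  nxt <- pop
  for (i in 1:3) {
    nxt <- vega_generation(nxt, fix$chromatogram, fix$windows, nm, cfg)
    # no new genetic material: every offspring value existed in the parents
    # (sampling with replacement may duplicate, but never invent)
    expect_length(setdiff(nxt$b, pop$b), 0)
  }
})

test_that("zero-generation runs return the best of the initial population", {
  fix <- small_ga_fixture()
  cfg <- ga_config(pop_size = 10, max_generations = 0, bits = 10, seed = 5)
  res <- optimize_b(fix$chromatogram, fix$windows, cfg,
                    b_grid = default_b_grid(8))
  expect_s3_class(res, "vega_result")
  expect_equal(res$generation_of_best, 0L)
  expect_equal(nrow(res$history), 1L)
  expect_equal(res$best_scalar,
               sum(res$best_objectives), tolerance = 1e-12)
})

test_that("the best-ever scalarised objective never increases", {
  fix <- small_ga_fixture()
  cfg <- ga_config(pop_size = 10, max_generations = 15, bits = 10,
                   stall_generations = 50, seed = 6)
  res <- optimize_b(fix$chromatogram, fix$windows, cfg,
                    b_grid = default_b_grid(8))
  expect_true(all(diff(res$history$best_scalar) <= 0))
  expect_true(res$best_b > 0 && res$best_b <= 1)
  # the reported optimum is the minimum the history ever saw
  expect_equal(res$best_scalar, min(res$history$best_scalar))
  # seeded replays reproduce the result exactly
  res2 <- optimize_b(fix$chromatogram, fix$windows, cfg,
                     b_grid = default_b_grid(8))
  expect_identical(res$best_b, res2$best_b)
  expect_identical(res$history, res2$history)
})

test_that("configuration constraints are enforced", {
  expect_error(ga_config(pop_size = 7, n_objectives = 2),
               class = "ssr_parameter_error")
  expect_error(ga_config(generation_gap = 0), class = "ssr_parameter_error")
  expect_error(ga_config(crossover_prob = 1.2), class = "ssr_parameter_error")
  expect_error(ga_config(mutation_prob = -0.1), class = "ssr_parameter_error")
})
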