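#' Genetic-algorithm configuration
#'
#' Defaults follow the settings used for the dye chromatograms: 100
#' individuals, at most 100 generations, 20-bit chromosomes and a generation
#' gap of 0.9 (90% of the population replaced by offspring each generation,
#' the best 10% of parents retained as elites). Crossover and mutation rates
#' take conventional GA values (single-point crossover at 0.7, per-bit flips
#' at 1/bits).
#'
#' @param pop_size Population size N; must be divisible by `n_objectives`.
#' @param max_generations Maximum number of generations.
#' @param bits Chromosome length L (precision of the encoded variable).
#' @param generation_gap Fraction of the population replaced by offspring.
#' @param crossover_prob Probability of single-point crossover per pair.
#' @param mutation_prob Per-bit flip probability (default `1/bits`).
#' @param seed Integer seed for the run, or `NULL` to leave the RNG alone.
#' @param n_objectives Number of objectives q (fixed at 2 here).
#' @param stall_generations Stop after this many generations without
#'   improvement of the best scalarised objective.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, max_generations = 100, bits = 20,
                      generation_gap = 0.9, crossover_prob = 0.7,
                      mutation_prob = 1 / bits, seed = NULL,
                      n_objectives = 2, stall_generations = 20) {
  if (pop_size < 2 || pop_size %% n_objectives != 0) {
    abort_ssr("pop_size must be >= 2 and divisible by n_objectives",
              "ssr_parameter_error")
  }
  if (generation_gap <= 0 || generation_gap > 1) {
    abort_ssr("generation_gap must be in (0, 1]", "ssr_parameter_error")
  }
  for (p in c(crossover_prob, mutation_prob)) {
    if (!is_number(p) || p < 0 || p > 1) {
      abort_ssr("probabilities must be in [0, 1]", "ssr_parameter_error")
    }
  }
  if (max_generations < 0 || bits < 1 || stall_generations < 1) {
    abort_ssr("counts must be positive", "ssr_parameter_error")
  }
  structure(
    list(
      pop_size = as.integer(pop_size),
      max_generations = as.integer(max_generations),
      bits = as.integer(bits),
      generation_gap = generation_gap,
      crossover_prob = crossover_prob,
      mutation_prob = mutation_prob,
      seed = seed,
      n_objectives = as.integer(n_objectives),
      stall_generations = as.integer(stall_generations)
    ),
    class = "ga_config"
  )
}

#' Decode a binary chromosome to the well steepness b
#'
#' With `k` the unsigned integer value of the bits (most significant bit
#' first), `b = (k + 1) / 2^L`, so the L-bit code covers `(0, 1]` exactly with
#' strict positivity: all-zeros maps to `2^-L`, all-ones to 1. Standard binary
#' coding, not Gray.
#'
#' @param bits Vector of 0/1 of length L.
#' @param L Expected chromosome length (default `length(bits)`).
#' @return Decoded b in `(0, 1]`.
#' @export
decode_bits <- function(bits, L = length(bits)) {
  if (length(bits) != L || !all(bits %in% c(0, 1))) {
    abort_ssr(sprintf("chromosome must be %d bits of 0/1", L), "ssr_encoding_error")
  }
  k <- sum(bits * 2^((L - 1):0))
  (k + 1) / 2^L
}

#' Proportional (roulette-wheel) selection for minimisation
#'
#' Samples `n_out` indices with replacement with probability proportional to
#' the nonnegative weight `w_i = (z_worst - z_i) + delta`, where `z` are the
#' objective values over the block, `z_worst` their maximum and
#' `delta = 0.01 * (z_worst - z_best) + 1e-12`. The worst-minus-value shift
#' makes smaller objectives fitter; the floor `delta` keeps every weight
#' positive and degrades to uniform sampling when all values are equal.
#' Scale- and shift-invariant in `z` up to the small floor.
#'
#' @param z Numeric vector of objective values (smaller is fitter).
#' @param n_out Number of draws.
#' @return Integer vector of `n_out` selected indices into `z`.
#' @export
proportional_select <- function(z, n_out) {
  if (length(z) == 0L) abort_ssr("empty selection block", "ssr_data_error")
  if (n_out == 0L) return(integer(0))
  z_worst <- max(z)
  z_best <- min(z)
  w <- (z_worst - z) + 0.01 * (z_worst - z_best) + 1e-12
  sample.int(length(z), n_out, replace = TRUE, prob = w)
}

# Population representation: bits is an N x L 0/1 matrix, b the decoded
# parameters, f1/f2 the objective values (NA until evaluated), t the
# generation index.
new_population <- function(bits, t = 0L) {
  N <- nrow(bits)
  L <- ncol(bits)
  b <- vapply(seq_len(N), function(i) decode_bits(bits[i, ], L), numeric(1))
  structure(
    list(bits = bits, b = b,
         f1 = rep(NA_real_, N), f2 = rep(NA_real_, N), t = t),
    class = "vega_population"
  )
}

random_population <- function(config) {
  bits <- matrix(
    sample(c(0L, 1L), config$pop_size * config$bits, replace = TRUE),
    nrow = config$pop_size
  )
  new_population(bits)
}

#' @export
print.vega_population <- function(x, ...) {
  cat(sprintf("<vega_population> N = %d, generation %d, %s\n",
              nrow(x$bits), x$t,
              if (anyNA(x$f1)) "unevaluated" else "evaluated"))
  invisible(x)
}

# Evaluate all individuals with NA objectives, caching by the integer value
# of the chromosome (offspring repeat codes often, and 2^20 codes map to the
# same objective evaluation every time).
evaluate_population <- function(pop, evaluator, cache) {
  todo <- which(is.na(pop$f1))
  for (i in todo) {
    key <- sprintf("%.0f", sum(pop$bits[i, ] * 2^((ncol(pop$bits) - 1):0)))
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- evaluator(pop$b[i])
      cache[[key]] <- hit
    }
    pop$f1[i] <- hit[1L]
    pop$f2[i] <- hit[2L]
  }
  pop
}

make_evaluator <- function(chrom, windows, normalizers, x0, subtract_median) {
  force(chrom); force(windows); force(normalizers)
  function(b) {
    obj <- objective_vector(b, chrom, windows, normalizers,
                            x0 = x0, subtract_median = subtract_median,
                            degenerate = "penalize")
    c(obj$f1, obj$f2)
  }
}

#' One VEGA generation
#'
#' Implements the vector-evaluated selection scheme: the evaluated population
#' is randomly permuted and partitioned into q contiguous blocks of N/q; from
#' block k, N/q parents are drawn by [proportional_select()] on objective k
#' alone; the pooled parents are shuffled, consecutive pairs undergo
#' single-point crossover with probability `crossover_prob`, then every bit
#' flips with probability `mutation_prob`. Elitism per the generation gap: the
#' `floor(N * (1 - generation_gap))` best parents by the scalarised objective
#' `f1 + f2` replace the worst offspring. Alternating selection pressure on
#' the two objectives maintains both high-SNR and symmetric-peak genotypes in
#' the population.
#'
#' @param pop An evaluated `vega_population`.
#' @param chrom Input [chromatogram()].
#' @param windows List of [peak_window()] objects.
#' @param normalizers Output of [compute_normalizers()].
#' @param config A [ga_config()].
#' @param cache Environment memoising objective evaluations by chromosome
#'   (optional; a fresh one is used if missing).
#' @param x0,subtract_median Passed to [rk4_enhance()].
#' @return The next generation, evaluated, with `t` incremented.
#' @export
vega_generation <- function(pop, chrom, windows, normalizers, config,
                            cache = new.env(parent = emptyenv()),
                            x0 = NULL, subtract_median = FALSE) {
  stopifnot(inherits(pop, "vega_population"), inherits(config, "ga_config"))
  if (anyNA(pop$f1) || anyNA(pop$f2)) {
    abort_ssr("population must be evaluated before breeding", "ssr_state_error")
  }
  N <- config$pop_size
  q <- config$n_objectives
  Ns <- N %/% q
  L <- config$bits

  # (i) random sort, (ii) contiguous blocks, (iii) per-objective selection
  perm <- sample.int(N)
  objectives <- cbind(pop$f1, pop$f2)[perm, , drop = FALSE]
  pool <- integer(0)
  for (k in seq_len(q)) {
    block <- ((k - 1) * Ns + 1):(k * Ns)
    chosen <- proportional_select(objectives[block, k], Ns)
    pool <- c(pool, perm[block][chosen])
  }

  # (iv) shuffle the mating pool, (v) crossover + mutation
  pool <- pool[sample.int(N)]
  bits <- pop$bits[pool, , drop = FALSE]
  for (p in seq(1L, N - 1L, by = 2L)) {
    if (stats::runif(1) < config$crossover_prob) {
      pt <- sample.int(L - 1L, 1L)
      tail1 <- bits[p, (pt + 1L):L]
      bits[p, (pt + 1L):L] <- bits[p + 1L, (pt + 1L):L]
      bits[p + 1L, (pt + 1L):L] <- tail1
    }
  }
  if (config$mutation_prob > 0) {
    flip <- matrix(stats::runif(N * L) < config$mutation_prob, nrow = N)
    bits[flip] <- 1L - bits[flip]
  }

  offspring <- evaluate_population(
    new_population(bits, t = pop$t + 1L),
    make_evaluator(chrom, windows, normalizers, x0, subtract_median),
    cache
  )

  # (vi) elitism: best parents by f1 + f2 replace the worst offspring
  n_elite <- floor(N * (1 - config$generation_gap))
  if (n_elite > 0) {
    elite <- order(pop$f1 + pop$f2)[seq_len(n_elite)]
    worst <- order(offspring$f1 + offspring$f2, decreasing = TRUE)[seq_len(n_elite)]
    offspring$bits[worst, ] <- pop$bits[elite, , drop = FALSE]
    offspring$b[worst] <- pop$b[elite]
    offspring$f1[worst] <- pop$f1[elite]
    offspring$f2[worst] <- pop$f2[elite]
  }
  offspring
}

#' Optimise the well steepness b by VEGA
#'
#' Searches `b` in `(0, 1]` minimising the two objectives (negated normalised
#' SNR sum, normalised asymmetry sum). Per-peak normalisers are pre-scanned on
#' a fixed grid ([compute_normalizers()]), then the population evolves by
#' [vega_generation()] until `max_generations`, or until the best scalarised
#' objective `f1 + f2` has not improved for `stall_generations` generations.
#' The reported optimum is the best-ever individual under `f1 + f2` (VEGA
#' itself imposes no single ranking; both objective values are returned).
#'
#' All randomness flows from `config$seed` when given, so runs replay exactly.
#'
#' @param chrom Input [chromatogram()].
#' @param windows List of [peak_window()] objects.
#' @param config A [ga_config()].
#' @param normalizers Optional precomputed [compute_normalizers()] output.
#' @param b_grid Grid for the normaliser pre-scan (default [default_b_grid()]).
#' @param x0,subtract_median Passed to [rk4_enhance()].
#' @return An object of class `vega_result`: `best_b`, `best_objectives`
#'   (f1, f2), `best_scalar`, `generation_of_best`, `history` (per-generation
#'   data frame), `normalizers`, `config`, `n_evaluations`.
#' @export
optimize_b <- function(chrom, windows, config = ga_config(),
                       normalizers = NULL, b_grid = default_b_grid(),
                       x0 = NULL, subtract_median = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(normalizers)) {
    normalizers <- compute_normalizers(chrom, windows, b_grid,
                                       x0 = x0, subtract_median = subtract_median)
  }
  cache <- new.env(parent = emptyenv())
  evaluator <- make_evaluator(chrom, windows, normalizers, x0, subtract_median)
  pop <- evaluate_population(random_population(config), evaluator, cache)

  best <- list(b = NA_real_, f1 = Inf, f2 = Inf, scalar = Inf, generation = 0L)
  take_best <- function(pop, best) {
    scalar <- pop$f1 + pop$f2
    i <- which.min(scalar)
    if (scalar[i] < best$scalar) {
      best <- list(b = pop$b[i], f1 = pop$f1[i], f2 = pop$f2[i],
                   scalar = scalar[i], generation = pop$t)
    }
    best
  }
  best <- take_best(pop, best)

  history <- data.frame(
    generation = 0L, best_scalar = best$scalar,
    gen_best_scalar = min(pop$f1 + pop$f2),
    mean_scalar = mean(pop$f1 + pop$f2), best_b = best$b
  )
  stall <- 0L
  for (t in seq_len(config$max_generations)) {
    pop <- vega_generation(pop, chrom, windows, normalizers, config,
                           cache = cache, x0 = x0,
                           subtract_median = subtract_median)
    prev <- best$scalar
    best <- take_best(pop, best)
    stall <- if (best$scalar < prev) 0L else stall + 1L
    history <- rbind(history, data.frame(
      generation = t, best_scalar = best$scalar,
      gen_best_scalar = min(pop$f1 + pop$f2),
      mean_scalar = mean(pop$f1 + pop$f2), best_b = best$b
    ))
    if (stall >= config$stall_generations) break
  }

  structure(
    list(
      best_b = best$b,
      best_objectives = c(f1 = best$f1, f2 = best$f2),
      best_scalar = best$scalar,
      generation_of_best = best$generation,
      history = history,
      normalizers = normalizers,
      config = config,
      n_evaluations = length(ls(cache))
    ),
    class = "vega_result"
  )
}

#' @export
print.vega_result <- function(x, ...) {
  cat(sprintf(
    paste0("<vega_result> best b = %.6g (generation %d)\n",
           "  f1 = %.5f, f2 = %.5f, f1 + f2 = %.5f\n",
           "  %d generations run, %d objective evaluations\n"),
    x$best_b, x$generation_of_best,
    x$best_objectives[["f1"]], x$best_objectives[["f2"]], x$best_scalar,
    max(x$history$generation), x$n_evaluations
  ))
  invisible(x)
}
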