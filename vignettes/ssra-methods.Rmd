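---
title: "Single-well stochastic resonance for weak chromatographic peaks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-well stochastic resonance for weak chromatographic peaks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrtrace)
```

## The model

`ssrtrace` treats a noisy chromatogram `I(t) = S(t) + N(t)` (pure signal
plus instrument noise) as the driving force of an overdamped Brownian
particle in the single-well quadratic potential `U(x) = -a + b x^2 / 2`:

$$\frac{dx}{dt} = -U'(x) + I(t) = -b\,x + I(t).$$

The particle displacement `x(t)` is the enhanced chromatogram. The offset
`a` cancels under differentiation and plays no role in the dynamics; it is
kept in `potential_params()` only so the well can be plotted. The single
steepness parameter `b` controls everything: the system is a first-order
linear filter with DC gain `1/b` and exponential memory `1/b` samples.
Physically, the "resonance" works because a peak is a slow, coherent push on
the particle while the noise is a fast, zero-mean jitter: integration lets
the peak accumulate while the noise averages out, so the windowed
signal-to-noise ratio of the output exceeds that of the input for a
well-chosen `b`.

Assumptions worth stating: the input trace is uniformly sampled; noise is
broadband relative to the peaks; peaks are slow relative to `1/b` samples.
When `b` is too small the output approaches a running integral of the trace
(all structure lost in drift), when `b` is too large the output approaches
`I(t)/b` (no averaging); the optimizer searches the useful region between
those extremes.

## The integrator

The Langevin equation is integrated with the classical fourth-order
Runge–Kutta scheme, one step per sample. Three numerical choices matter.

**Time is counted in sample units.** `b` is a per-sample rate, so its
admissible range `(0, 1]` is meaningful regardless of the sampling rate.
A numeric value of `b` is therefore tied to the sampling rate: at 10 Hz,
`b = 0.0171` corresponds to a memory of `1/b ≈ 58` samples ≈ 5.8 s. The
`h` argument of `rk4_enhance()` exposes the step size for users who prefer
another time coordinate (the convergence tests integrate with `h` equal to
the physical sample spacing).

**The half-step input is interpolated at fourth order.** RK4's middle
stages need `I(t + h/2)`, which falls between samples. Averaging the two
bracketing samples is the obvious choice but is only second-order accurate
and silently degrades the whole scheme to order 2. The package instead uses
the cubic four-point interpolation
`(-u[n-1] + 9u[n] + 9u[n+1] - u[n+2])/16` in the interior and a one-sided
quadratic at the two boundary steps, which preserves the scheme's fourth
order (measured empirical order ≈ 4.0 against the exact convolution
solution for an exponential input). Because the drift is linear, the k1–k4
update collapses algebraically to an exact one-pole recurrence
`x[n+1] = A x[n] + c0 I[n] + cm Imid[n] + c1 I[n+1]`, which is what the code
evaluates (via `stats::filter`); the test suite checks it against a literal
k1–k4 loop to 1e-10.

**The particle starts at equilibrium.** With a zero initial state and a
nonzero baseline, the output climbs toward `baseline/b` with time constant
`1/b` samples. At small `b` this warm-up transient is large and slow enough
to dominate the standard deviation of early baseline windows and distort
the optimizer's objective (on the packaged fixture it reversed the first
peak's apparent enhancement). The default initial state is therefore the
steady state of the first input sample, `x0 = I[1]/b` — the usual warm-up
convention for recursive filters. `x0` remains numerically configurable.
Superposition is unaffected because the initial state is linear in the
input. Relatedly, the `1/b` DC gain amplifies any baseline offset;
`subtract_median = TRUE` removes the input median first (off by default, as
the chord baseline correction in the metrics already makes them
offset-invariant).

RK4's linear stability bound (`|h b| < 2.785`) is never approached for
admissible `b`, so the output is finite for every candidate the optimizer
can produce.

## Peak metrics

Peak windows are user-supplied (retention times are known in targeted
analysis): a signal range containing the peak and a disjoint, nearby flat
baseline range, each at least 3 samples.

- **SNR** is the sample SD over the signal range divided by the sample SD
  over the baseline range. The n−1 denominator is used — the conventional
  choice for noise estimation on finite windows. The ratio is invariant
  under vertical scaling of the trace.
- **Asymmetry (SYN)** first subtracts the chord joining the signal range's
  endpoint samples (a deterministic baseline correction that absorbs the DC
  and linear components the enhancement amplifies), splits the corrected
  peak at its apex — the earliest maximum, which must be interior to the
  range — and returns `|LA/RA - 1|` from the left and right trapezoidal
  areas, the apex sample bounding both. A mirror-symmetric peak scores
  exactly 0.
- **Peak area** for quantitation is the same chord-corrected trapezoid over
  the whole signal range, `LA + RA`.

The two optimization objectives divide each peak's metrics by per-peak
maxima `SNR_i^max`, `SYN_i^max`. These are pre-scanned once, before the
search, on a fixed geometric grid of 64 values of `b` spanning
`[2^-20, 1]` — the dynamic range of the 20-bit encoding. Scanning once
keeps the objectives stationary across generations (normalising within
each generation would make fitness values incomparable between
generations); 64 points resolve the smooth SNR/SYN curves comfortably. A
zero maximum disables normalisation for that term rather than dividing by
zero.

At extreme candidates (very small `b`) a window can become degenerate — the
quasi-integrated trace puts the apex on a window boundary. During
optimization such a candidate is scored at the worst admissible values
(SNR 0, asymmetry at its normaliser) so it is dominated rather than fatal;
outside the optimizer the same condition raises a classed error carrying
the peak id.

## The VEGA optimizer

The two objectives `f1 = -Σ SNR_i/SNR_i^max` (minimised) and
`f2 = Σ SYN_i/SYN_i^max` (minimised) are searched by a vector-evaluated
genetic algorithm: each generation the population is randomly permuted,
split into two contiguous halves, and each half is sampled by roulette
selection under *one* objective; the pooled parents are shuffled, crossed
over and mutated. Alternating the selection pressure maintains both
high-SNR and symmetric-shape genotypes without any Pareto bookkeeping.

Concrete choices, several of which fill gaps the classical description
leaves open:

- **Encoding.** 20-bit standard binary chromosomes decode as
  `b = (k+1)/2^20`, covering `(0, 1]` exactly with strict positivity.
  Defaults: 100 individuals, at most 100 generations, generation gap 0.9.
- **Selection weights.** Roulette selection needs nonnegative weights and
  smaller-is-better here, so within a block the weight is
  `(z_worst - z_i) + δ` with `δ = 0.01 (z_worst - z_best) + 1e-12`:
  shift-invariant, strictly positive, and uniform when the block is flat.
- **Variation.** Single-point crossover with probability 0.7 and per-bit
  mutation at `1/L = 0.05` — conventional rates, configurable.
- **Generation gap.** 0.9 is read as "90% of the population replaced": the
  best `floor(0.1 N)` parents under the scalarised objective `f1 + f2`
  survive, replacing the worst offspring. VEGA defines no single ranking,
  so the scalar sum is used for elitism, for the stopping rule, and for
  reporting the final optimum (both objective values are always returned).
- **Stopping.** At most `max_generations`, or 20 consecutive generations
  without improvement of the best-ever scalar.
- **Determinism.** All randomness flows from one seed recorded in the
  configuration; repeated runs are bit-identical. Objective evaluations are
  memoised by chromosome (the 20-bit space is small and offspring repeat),
  which typically cuts evaluations several-fold.

The primary correctness oracle is exhaustive search: on the packaged
fixture the GA's best scalar matches (in practice slightly beats, since it
is not confined to the grid) the minimum over 1,000 log-spaced values
of `b`.

## The synthetic generator

No experimental traces ship with the package, so a generator provides
fixtures with exact ground truth `I = S + N`. It emulates a weak five-dye
HPLC trace: 0–30 min at 10 Hz, analysed over 2–29 min (16,201 samples),
peaks at 4.5, 6.0, 10.4, 15.8 and 25.9 min. Peak shapes are Gaussian or
exponentially modified Gaussian — the standard model for column tailing —
with widths growing with retention (σ = 3–7.5 s, τ = 0–3 s) as in gradient
separations. The EMG is evaluated in log space (`pnorm(log.p = TRUE)`), so
it neither overflows nor goes negative anywhere; `τ ≤ 1e-4 σ` falls back to
the Gaussian limit where the EMG expression loses floating-point precision.
Heights (5–7 units against unit white noise over a flat baseline of 10)
put the raw windowed SNR near 2–3, i.e. peaks visibly present but too weak
for reliable quantitation — the regime the method targets. The
seven-level dilution series (relative concentrations 1, 1.5, 2, 2.5, 3, 4,
5) scales those heights for end-to-end calibration tests.

What the generator does *not* emulate: 1/f and drift-correlated noise,
detector saturation, co-eluting interferents, retention-time jitter between
dilution levels. Passing tests therefore demonstrate the algorithmic
machinery under stationary Gaussian noise, not robustness to every
instrumental artefact; on real traces the baseline windows should be chosen
in genuinely flat regions, exactly as a practitioner would.

## Calibration statistics

`fit_calibration_line()` fits `A = slope·c + intercept` by OLS and reports
the conventions of chromatographic method validation: ± values are standard
errors of the coefficients, `r` is the Pearson correlation of concentration
and area, and the residual SD uses n−2 degrees of freedom. These
conventions reproduce, to printed precision, all 30 statistics of the
bundled five-dye, seven-level series (`sudan_calibration()`), which is the
package's exact end-to-end regression check. Quantitation across a dilution
series must use one fixed `b` for every level — the enhancement is linear
in the input, so a common `b` preserves proportionality between
concentration and enhanced area (the packaged series gives r > 0.998 for
all five peaks).

## Problem sizes and runtime

The test suite exercises the full 16,201-sample fixture for the optimizer
and acceptance checks and a 481-sample two-peak trace for GA mechanics;
the complete suite runs in well under a minute on one CPU, and
`scripts/acceptance.R` (full GA plus 1,000-point grid search plus the
dilution series) in about half a minute. These sizes were chosen to mirror
the real data geometry while keeping iteration fast.

## Known limitations

- `b` values are tied to the per-sample convention; transferring a value
  between sampling rates requires rescaling by the rate ratio.
- Windows are fixed in time; strongly retention-shifted replicates would
  need re-windowing before metrics are computed.
- The asymmetry score uses the apex-sample split and chord baseline; peaks
  whose apex falls on a window edge (severely fronting/tailing windows, or
  near-integral outputs at extreme `b`) are reported as degenerate rather
  than scored.
- VEGA returns the scalar-best compromise, not a Pareto front; users who
  want the full SNR-vs-shape trade-off can evaluate `objective_vector()`
  over a grid of `b`.
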