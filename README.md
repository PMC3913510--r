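# ssrtrace

Stochastic-resonance enhancement of weak chromatographic peaks, with
multi-objective genetic-algorithm tuning of the single system parameter.

## The problem

In HPLC trace analysis — dye adulterants, drug residues, contaminants at
ng/mL levels — the peaks of interest often sit barely above the detector
noise. Conventional filtering removes noise and signal together. The
single-well potential stochastic resonance algorithm (SSRA) instead feeds the
noisy chromatogram `I(t)` as the driving force of an overdamped Brownian
particle in a quadratic potential:

```
dx/dt = -U'(x) + I(t),    U(x) = -a + (1/2) b x^2
```

so the equation of motion is `dx/dt = -b x + I(t)`. The particle trajectory
`x(t)` is the output chromatogram: slow peak components are amplified (DC
gain `1/b`) while broadband noise is averaged away, raising the windowed
signal-to-noise ratio of every peak at once. Only the well steepness `b`
(constrained to `0 < b <= 1`, expressed per sample) has to be chosen.

Choosing `b` for several peaks at once is a trade-off between amplification
and peak shape, so `ssrtrace` tunes it with a vector-evaluated genetic
algorithm (VEGA) minimising two objectives over all `n` peaks:

```
f1(b) = -sum_i SNR_i(b) / SNR_i^max     (signal-to-noise)
f2(b) =  sum_i SYN_i(b) / SYN_i^max     (peak asymmetry)
```

where `SNR_i` is the SD of the trace over peak i's signal window divided by
the SD over its baseline window, and `SYN_i = |LA_i/RA_i - 1|` measures the
areal imbalance of the two peak halves about the apex. The per-peak maxima
are pre-scanned on a fixed grid of `b` values so every peak contributes on a
comparable scale.

The package provides chromatogram I/O, the Runge–Kutta SSRA engine, the
peak metrics, the VEGA optimizer, peak-area quantitation with OLS
calibration lines, a ground-truth synthetic chromatogram generator, and a
command-line interface. It is aimed at analytical chemists and method
developers working on multicomponent trace quantitation.

## Worked example

Optimise `b` on a seeded synthetic five-peak chromatogram (16,201 samples,
2–29 min at 10 Hz, raw peak SNR ≈ 2, emulating a weak azo-dye trace):

```r
library(ssrtrace)

fix <- sudan_like_fixture(seed = 42)
result <- optimize_b(fix$chromatogram, fix$windows, ga_config(seed = 42))
result
#> <vega_result> best b = 0.00461578 (generation 3)
#>   f1 = -3.91507, f2 = 0.01720, f1 + f2 = -3.89786
#>   23 generations run, 1771 objective evaluations

enhanced <- rk4_enhance(fix$chromatogram, result$best_b)
cbind(raw      = sapply(fix$windows, function(w) snr_of_peak(fix$chromatogram, w)),
      enhanced = sapply(fix$windows, function(w) snr_of_peak(enhanced, w)))
#>       raw enhanced
#> [1,] 2.31     8.99
#> [2,] 2.53    27.68
#> [3,] 2.01    21.12
#> [4,] 2.46    39.98
#> [5,] 1.87    27.24
```

`f1 = -3.92` means the optimum holds the five peaks at an average 78% of
their individually best achievable SNR simultaneously, while `f2 = 0.017`
says the residual asymmetry is near its achievable minimum; every peak's SNR
rises 4–16-fold over the raw trace.

Calibration lines from the bundled seven-level dye series (concentration in
ng/mL vs enhanced peak area):

```r
tab <- calibration_table(sudan_calibration())
cat(paste(tab$label, tab$equation, sep = ": "), sep = "\n")
#> para_red: A = (156.1 ± 6.999)c + (1231 ± 303.6), r = 0.9950, SD = 348.1
#> sudan_i: A = (125.5 ± 3.575)c + (1599 ± 219.6), r = 0.9980, SD = 251.9
#> sudan_ii: A = (96.2 ± 2.178)c + (3150 ± 329.2), r = 0.9987, SD = 377.6
#> sudan_iii: A = (161.1 ± 5.481)c - (307.1 ± 815.5), r = 0.9971, SD = 935.2
#> sudan_iv: A = (61.77 ± 2.273)c + (1171 ± 829.8), r = 0.9966, SD = 951.6
```

The ± values are standard errors, `r` is the Pearson correlation of
concentration and area, and SD is the residual standard deviation
(n−2 degrees of freedom).

## Command line

The same four steps are scriptable through `inst/scripts/ssrtrace`
(or `ssra_main()` from R):

```sh
ssrtrace simulate --out trace.csv --windows windows.yaml --seed 42
ssrtrace enhance  --in trace.csv --out enhanced.csv --b 0.0171
ssrtrace optimize --in trace.csv --windows windows.yaml --seed 42 --out history.csv
ssrtrace calibrate --in series.csv --out fits.csv
```

Traces are two-column CSV (time in minutes, intensity), windows a small YAML
file; every file-producing run writes a `.run.json` replay summary. Exit
codes: 0 success, 1 data/parameter error, 2 usage error.

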