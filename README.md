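# fretkin

Single-molecule FRET trace analysis and dwell-time kinetics for
surface-tethered molecular complexes, with a matched synthetic-data
generator for end-to-end validation.

The motivating system is the disassembly of the neuronal SNARE complex by
the AAA+ ATPase NSF with its αSNAP adapters, watched one complex at a time
by total internal reflection (TIRF) smFRET: an assembled complex holds its
donor and acceptor dyes close (high FRET efficiency, E ≈ 0.8), partial
disassembly separates them (E ≈ 0.2), and inhibitors such as complexin
show up as molecules that never leave the high-FRET state. The package
implements the complete analysis chain for this class of experiment:

- **Trace preparation** — linear 2×2 unmixing of donor/acceptor channel
  cross-talk, FRET efficiency `E = I_A / (I_A + I_D)`, per-molecule bright
  levels (`fret_frames()`).
- **Classification** — automated photobleach detection (a conformational
  transition returns to high FRET; a bleach never recovers) and sorting of
  every molecule into `with_transitions` / `without_transitions` /
  `excluded`, plus the per-field *fraction without transitions*, the
  assay's activity readout (`classify_traces()`,
  `fraction_without_transitions()`).
- **Idealization** — per-molecule hidden Markov models with Gaussian
  emissions, fitted by Baum–Welch EM with a C++ core and decoded by
  Viterbi (`fit_hmm()`, `fit_hmm_all()`, `idealized_paths()`).
- **Kinetics** — interior ("section II") dwell extraction, linear and
  log-timescale dwell histograms, data-driven short/long-lived population
  partitioning, and first-order exponential rate fits by least squares or
  truncated-MLE (`extract_dwells()`, `find_partition_threshold()`,
  `fit_exponential_rate()`).
- **Binding** — equilibrium isotherm and single-site competition models
  with per-field spot-count normalization (`fraction_bound()`,
  `competitive_occupancy()`, `normalize_competition()`).
- **Simulation** — a Gillespie continuous-time Markov chain simulator
  with camera-integration frame averaging, stochastic two-site dye
  labeling, irreversible photobleaching, channel leakage and Gaussian
  noise, returning a ground-truth ledger for every molecule
  (`sim_config()`, `simulate_experiment()`).

All functions take and return tibbles keyed by `molecule_id` / `field_id`;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a three-field experiment at the reference conditions (10 Hz,
200 s traces, σ/total = 0.08 channel noise, leakage 1.7%/16.5%, mean
high-state dwell ≈ 14.3 s) and run the full pipeline:

```r
library(fretkin)

sim <- sim_config(n_fields = 3, n_molecules_per_field = 40, seed = 11)
res <- simulate_experiment(sim)
ts  <- trace_set(res$traces, frame_rate = sim$frame_rate)
ts
#> <trace_set> 68 molecules, 136000 frames total, 10 Hz
#> # A tibble: 136,000 × 6
#>    molecule_id field_id frame donor acceptor  time
#>    <chr>       <chr>    <int> <dbl>    <dbl> <dbl>
#>  1 F01_m002    F01          0 1988.     44.7   0
#>  2 F01_m002    F01          1 2035.    -13.8   0.1
#>  3 F01_m002    F01          2 1869.    118.    0.2
#> # ℹ 135,997 more rows

out <- run_analyze(ts, run_config(seed = 11))
out$counts
#> # A tibble: 7 × 2
#>   stage                   n
#>   <chr>               <int>
#> 1 total_molecules        68
#> 2 excluded               31
#> 3 without_transitions     2
#> 4 with_transitions       35
#> 5 hmm_fitted             35
#> 6 hmm_refused             0
#> 7 dwells                164
```

Only 68 of the 120 seeded molecules are donor-visible (stochastic
labeling), and exclusions cover donor-only spots, traces bleaching too
early, and multi-complex spots. The fraction of molecules without
transitions — the inhibition readout — is reported per field, mean ± SD:

```r
out$fraction$summary
#> # A tibble: 1 × 3
#>     mean     sd n_fields
#>    <dbl>  <dbl>    <int>
#> 1 0.0303 0.0525        3
```

Dwell populations and the disassembly rate from the long-lived high-FRET
dwells:

```r
out$partition
#> # A tibble: 2 × 8
#>   state_label threshold short_mean short_sd long_mean long_sd n_dwells n_fields
#>   <chr>           <dbl>      <dbl>    <dbl>     <dbl>   <dbl>    <int>    <int>
#> 1 high             0.56     0.0348   0.0326     0.965  0.0326       78        3
#> 2 low              0.32     0.0516   0.0451     0.948  0.0451       86        3

out$rate
#> <rate_fit> lsq: rate 0.0880 s^-1 (mean dwell 11.36 s), n = 75 beyond 0.56 s
```

With only 75 usable dwells the rate estimate is noisy; at the test-suite
scale (2000 dwells) the same estimator recovers the generative 14.3 s
mean dwell within 10%.

Equilibrium occupancy of the adapter-binding isotherm (Kd = 1.5 µM):

```r
round(fraction_bound(c(0.5, 2, 20), kd = 1.5), 4)
#> [1] 0.2500 0.5714 0.9302
```

A command-line front end with `simulate`, `analyze`, `binding` and
`report` subcommands is installed under
`system.file("scripts", "fretkin-cli.R", package = "fretkin")`.

## Testing

```r
testthat::test_dir("tests/testthat", package = "fretkin",
                   load_package = "installed")
```

The suite covers unit oracles (hand-solved unmixing, closed-form
exponential fractions, Viterbi versus exhaustive path enumeration),
property tests (round trips, EM log-likelihood monotonicity, estimator
bias under truncation), and end-to-end runs checked against the
simulator's ground-truth ledger.

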