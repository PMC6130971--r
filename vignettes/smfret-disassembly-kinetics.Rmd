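---
title: "Methods: smFRET trace analysis and disassembly kinetics with fretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET trace analysis and disassembly kinetics with fretkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
library(dplyr)
```

fretkin analyzes single-molecule FRET (smFRET) time traces of
surface-tethered molecular complexes — the motivating system is
NSF/αSNAP-mediated disassembly of the neuronal SNARE complex — and ships a
matched synthetic-data generator so every stage of the pipeline can be
validated against known ground truth. This vignette documents the model,
the fixed assay constants, the numerical choices, and the limits of the
approach.

## The measurement model

Each surface-tethered molecule carries (at most) one donor and one
acceptor dye. At every camera frame the two detection channels record
intensities $I_D$ and $I_A$; a fraction of each dye's emission leaks into
the other channel. With leakage fractions $l_{DA}$ (donor into acceptor)
and $l_{AD}$ (acceptor into donor) the observed intensities are a linear
mixture of the true ones,

$$
\begin{pmatrix} I_D^{obs} \\ I_A^{obs} \end{pmatrix} =
\begin{pmatrix} 1 - l_{DA} & l_{AD} \\ l_{DA} & 1 - l_{AD} \end{pmatrix}
\begin{pmatrix} I_D \\ I_A \end{pmatrix},
$$

which `correct_leakage()` inverts exactly (the matrix is singular only
when $l_{DA} + l_{AD} = 1$, far outside any physical regime). The FRET
efficiency proxy is then $E = I_A / (I_A + I_D)$ on the corrected
intensities (`compute_fret()`). Frames whose summed intensity falls below
a floor (default 20% of the molecule's bright level) give unreliable
ratios and are flagged `NA`.

The assembled complex holds the dyes close (high $E \approx 0.8$);
partial disassembly separates them (low $E \approx 0.2$). A molecule's
$E$ trace is therefore modeled as a two-state (optionally three-state)
continuous-time Markov process observed at the camera rate through
Gaussian noise.

## Fixed assay constants

All constants live in `run_config()` as *defaults* — every pipeline stage
takes them as arguments, nothing is hard-coded.

| Constant | Default | Rationale |
|---|---|---|
| Frame rate | 10 Hz | camera integration time of the assay |
| Trace length | 200 s | movie duration |
| Leakage $l_{DA}$, $l_{AD}$ | 0.017, 0.165 | calibrated channel cross-talk |
| State boundary | $E = 0.5$ | separates low/high FRET states |
| HMM initial means | 0.2 / 0.8 (2-state), 0.2 / 0.5 / 0.8 (3-state) | nominal state efficiencies |
| Short/long partition | 0.56 s (high), 0.32 s (low) | minima of the log-timescale dwell histograms |
| Exponential-fit domain | $t \ge 0.56$ s | excludes the short-lived population |
| Minimum analyzable frames | 20 | below this an HMM fit is refused |

## Trace classification and photobleaching

Terminal photobleaching of the acceptor mimics a high-to-low FRET
transition; the discriminating criterion is *recovery*: a genuine
conformational excursion returns to high FRET, a bleach never does.
`detect_bleach_and_section()` works on running-median smoothed channels
(window 9 frames):

* **Donor bleach** — first frame after which the summed intensity never
  again exceeds 50% of the molecule's bright level in a sustained way.
* **Acceptor bleach** — first frame (while the donor persists) after
  which the acceptor channel never again exceeds 12% of the bright level.
* A "recovery" shorter than the smoothing window does not count: a live
  fluorophore stays bright for many frames, whereas noise excursions that
  survive a running median last about one smoothing window. Without this
  rule, a single smoothed-noise spike in a 2000-frame trace breaks the
  suffix-maximum criterion.

Each molecule ends in exactly one category: `with_transitions`,
`without_transitions` (constant high FRET until bleach — the signature of
an inhibited complex), or `excluded` (no co-localized acceptor, too few
pre-bleach frames, or a bright level exceeding 1.5× the field median,
indicating several complexes under one diffraction-limited spot). The
headline statistic, `fraction_without_transitions()`, is computed per
field of view over all donor-visible molecules and summarized as
mean ± SD across fields.

The pre-bleach trace is divided into three sections: section I is the
first dwell (entry time unknown), section III the final dwell (its end
may be bleaching rather than a conformational step), and section II
everything in between. **Only section II dwells enter kinetics**; this is
implemented by dropping the first and last run of every idealized path in
`extract_dwells()`.

## HMM idealization

`fit_hmm()` implements Baum–Welch expectation–maximization for a hidden
Markov model with Gaussian emissions, followed by Viterbi decoding. The
numerical core (scaled forward–backward and log-space Viterbi) is written
in C++ via Rcpp for speed; per-frame emission log-densities are offset by
their row maximum before exponentiation so that arbitrarily unlikely
frames cannot underflow. Choices and safeguards:

* Convergence: relative log-likelihood change below `1e-6`, at most 500
  iterations; the full log-likelihood trace is kept so monotonicity is
  testable.
* A floor of `1e-3` on emission standard deviations prevents variance
  collapse onto single frames.
* After fitting, states are sorted by mean so state 1 is always the
  lowest-FRET state (label switching).
* States occupied less than one expected frame are flagged `degenerate`
  rather than silently reported.
* Traces with fewer than 20 analyzable frames raise a classed error
  (`fretkin_error_too_few_frames`); `fit_hmm_all()` logs and skips such
  molecules instead of aborting a run.

## Dwell-time kinetics

Dwell durations from the idealized paths are histogrammed on linear
(1 s bins) and logarithmic (0.25 log₁₀ bins) timescales. Two dwell
populations — short- and long-lived — are separated at the interior
minimum of the smoothed log-timescale histogram between its two largest
modes (`find_partition_threshold()`, 3-bin moving average); when the
histogram is unimodal the assay default (0.56 s high state, 0.32 s low
state) is used and flagged. Dwells strictly below the threshold are
short-lived; population fractions are per-field mean ± SD.

The disassembly rate comes from the long-lived high-FRET dwells via
`fit_exponential_rate()`:

* `"lsq"` (default, mirroring the histogram procedure): nonlinear least
  squares of $A e^{-kt}$ on the linear histogram counts over bins with
  centers ≥ 0.56 s, with log-linear starting values.
* `"mle"`: the left-truncated exponential maximum-likelihood estimator
  $k = 1/(\overline{t \ge t_0} - t_0)$, unbiased under truncation and
  recommended as a cross-check.

## The synthetic-data generator

`sim_config()` / `simulate_experiment()` generate traces by the same
physics the pipeline assumes, plus the artifacts it must be robust to:

* Conformational dynamics: exact Gillespie simulation of the
  continuous-time Markov chain; default rates 0.07 s⁻¹ (high→low) and
  0.1 s⁻¹ (low→high), i.e. a mean high-state dwell of ~14.3 s. Molecules
  start in the highest-FRET (assembled) state.
* Camera integration: each frame's ideal efficiency is the time average
  of the piecewise-constant path over the frame, so transition-spanning
  frames take intermediate values — as in real data.
* Photophysics: irreversible exponential bleaching of each dye (defaults
  0.005 s⁻¹ donor, 0.01 s⁻¹ acceptor). Acceptor bleach reroutes the full
  total intensity to the donor; donor bleach zeroes both channels.
* Stochastic labeling of the two dye sites (efficiency 0.9 per site,
  donor/acceptor ratio 0.5), producing the realistic mixture of
  FRET-capable, donor-only, acceptor-only and unlabeled molecules.
* Additive Gaussian channel noise (σ = 80 counts on a total of 1000,
  i.e. σ/total = 0.08) and linear channel leakage.
* Reproducibility: each molecule draws from its own deterministic RNG
  substream, so any field or molecule can be regenerated independently.

Every simulation returns a ground-truth ledger (labeling class, bleach
times, pre-bleach transition count and high-state occupancy, expected
classification) against which the pipeline is tested end-to-end.

What the generator does **not** emulate: dye blinking and spectral
fluctuations, diffusive background and neighboring-spot bleed-through,
stage drift, nonlinear detector response, and triplet-state photophysics.
Bleaching is strictly irreversible; thus the "never recovers" criterion
is exactly correct for synthetic data and only approximately so for real
recordings.

## Validation problem sizes

The package's own test suite validates, at sizes chosen to run in minutes
on one CPU: Viterbi against exhaustive path enumeration (200 random
instances, ≤ 12 frames); EM log-likelihood monotonicity; state-mean
recovery within 0.02 mean absolute error over 100 simulated molecules at
reference noise; the 14.3 s mean dwell recovered within 10% from 2000
censored synthetic dwells; the closed-form short-lived fraction
$1 - e^{-0.56/14.3} \approx 3.8\%$ within 3 standard errors at $n = 10^4$;
mix→unmix and file round-trip identities; and a full simulate→analyze run
reproducing ledger classifications for ≥ 95% of molecules. Ground-truth
dwell means in the end-to-end check are computed from truth paths
*truncated at each molecule's bleach time*, because only dwells completed
while both dyes are alive are observable.

## Design decisions

* **Tabular, tidyverse-native interfaces.** Every stage takes and returns
  tibbles keyed by `molecule_id`/`field_id`, so pipelines compose with
  dplyr; fitted objects (`hmm_fit`, `rate_fit`, `fret_mixture`) have
  `tidy()`/`glance()` methods and ggplot2 `autoplot()`s.
* **Bulk trace format.** Plain CSV/TSV with a one-line `#` metadata
  header is canonical; Apache Parquet (via the optional `arrow` package)
  is the compact binary alternative for large trace sets.
* **Full 2×2 unmixing** rather than the common donor-only leakage
  subtraction: it is exact, symmetric in the two channels, and reduces to
  the simple correction when $l_{AD} = 0$.
* **Automated, per-molecule bleach detection** with conservative
  exclusion rules, rather than manual trace curation — required for
  reproducibility and testability.
* **Simulation defaults are the reference conditions**; parameters exist
  to explore other regimes, not to tune results.

## Limitations

* The Gaussian-emission HMM ignores the beta-like distribution of ratio
  noise near $E = 0$ or $1$; at reference noise levels the approximation
  is excellent, at very low intensity it is not.
* Dwells are integer multiples of the frame interval; rates approaching
  the frame rate are underestimated because sub-frame excursions are
  averaged away by camera integration.
* The two-population partition assumes well-separated timescales; when
  the log-timescale histogram is unimodal the threshold falls back to the
  assay default and downstream fractions inherit that choice.
* Section III dwells are discarded rather than treated as right-censored
  observations; a survival-analysis treatment could use them but would
  couple the kinetics to the bleach-rate estimate.
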