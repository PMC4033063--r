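# synergait

Motor module (muscle synergy) extraction from multi-channel surface EMG
recorded during walking.

When humans walk, the nervous system appears to recruit muscles in a small
number of coordinated groups rather than one by one. Given envelopes of
$M$ muscles' EMG over the step cycle, non-negative matrix factorization
(NMF) decomposes them as

$$X(k) \approx X_r(k) = S\,P(k), \qquad N < M,$$

where the columns of $S$ (muscle weightings) are the motor modules and
$P(k)$ are their activation signals across the cycle. Reconstruction quality
is measured by the variance accounted for, $\mathrm{VAF} = 1 -
\mathrm{SSE}/\mathrm{SST}$ (uncentered). A practical question for anyone
applying this to gait — biofeedback, rehabilitation robotics, basic motor
control — is how the *data structure* fed to NMF affects the result: single
step cycles (EMG~SNG~), the average of k consecutive cycles (EMG~AVR~), or
their concatenation (EMG~CNC~), and how many cycles are enough.

`synergait` implements the full analysis chain for that question, plus a
seeded synthetic gait-EMG generator so every stage can be validated against
known ground truth:

* **Preprocessing** — zero-lag Butterworth filtering, linear envelopes
  (20–500 Hz band-pass, rectification, 10 Hz low-pass), step-cycle
  segmentation from a tibial accelerometer, time normalization to a
  200-point cycle grid, peak normalization.
* **Data structures** — SNG / AVR / CNC construction for any cycle count
  and offset.
* **Factorization** — Lee–Seung multiplicative-update NMF (best of
  restarts), fixed-weightings and fixed-activations variants, VAF reports,
  random-factor baselines.
* **Module analysis** — normalized scalar-product similarity, globally
  optimal best-pair matching, VAF-curve dimensionality selection, averaging
  of matched factorizations.
* **Study pipeline** — a 12-subject synthetic cohort run emitting tidy
  tables: VAF by structure and cycle count, intra-/cross-structure module
  similarity, and fixed-weightings cross-reconstruction.
* **Synthetic data** — subjects generated from a 5-module ground truth with
  controllable step-to-step amplitude, timing and noise variability,
  rendered down to raw carrier-modulated EMG plus an accelerometer channel.

## Worked example

```r
library(synergait)

rec <- generate_subject(simulation_config(seed = 42))
rec
#> <recording> 10 channels x 89015 samples @ 2000 Hz (44.5 s)
#>   41 true cycle boundaries

set <- preprocess_recording(rec)   # envelope -> segment -> 200-point cycles
set
#> <step_cycle_set> 40 cycles x 10 muscles x 200 points

fit <- nmf(concatenated_cycles(set, 40), n_modules = 5, seed = 1)
fit
#> <factorization_result> 10 muscles x 5 modules, T = 8000
#>   VAF = 0.9930 after 660 iterations (best of 20 restarts)

sel <- select_dimensionality(concatenated_cycles(set, 40), n_max = 8,
                             restarts = 10, seed = 1)
sel$n
#> [1] 5

round(match_modules(fit$S, rec$ground_truth$weightings)$similarities, 2)
#> [1] 0.99 1.00 0.96 0.98 0.99
```

Five modules reconstruct ~99% of the signal energy, the VAF-elbow rule picks
N = 5, and each extracted weighting vector matches its generating module
(normalized scalar product 0.96–1.00).

The full study runs as:

```r
tables <- run_cohort(n_subjects = 12, seed = 1)   # ~6 min on one CPU
write_study_tables(tables, "study_out")            # 4 CSVs + manifest.json
```

A thin command-line wrapper covering simulate / preprocess / build /
extract / select-dim / similarity / reconstruct / run-study is installed at
`system.file("cli.R", package = "synergait")`.

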