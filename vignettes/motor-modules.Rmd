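---
title: "Extracting motor modules from locomotion EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting motor modules from locomotion EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## The model

Surface EMG envelopes recorded from $M$ muscles during walking are modeled as
a nonnegative mixture of a small number $N < M$ of motor modules:

$$X(k) \approx X_r(k) = S \, P(k)$$

where $X(k)$ is the $M \times T$ matrix of envelope samples, $S$ is the
$M \times N$ synergy (muscle weighting) matrix, and $P(k)$ the $N \times T$
activation signals. `nmf()` estimates $S$ and $P$ by the Lee–Seung
multiplicative update rules for the squared Frobenius error, which preserve
nonnegativity and never increase the objective. Reconstruction quality is the
variance accounted for,

$$\mathrm{VAF} = 1 - \mathrm{SSE}/\mathrm{SST},$$

with SST the *uncentered* total sum of squares $\sum X^2$ pooled over all
muscles and samples — the dominant convention in the synergy literature; the
centered variant is available via `vaf(..., centered = TRUE)` for sensitivity
analysis.

Because NMF is scale-indeterminate, results are canonically normalized:
columns of $S$ are max-normalized with compensating row scaling of $P$. This
makes weighting vectors comparable across runs, subjects and data structures;
similarity comparisons themselves use the normalized scalar product and are
scale-free either way.

## The analysis chain

1. **Envelope** (`emg_envelope`): 20–500 Hz band-pass, full-wave
   rectification, 10 Hz low-pass. All filters are second-order Butterworth
   designs applied forward–backward (`zero_lag_butterworth`), i.e. zero phase
   lag at the cost of squaring the magnitude response; the literature rarely
   states whether a quoted order refers to the design or the effective
   response, and we commit to the design order. Forward–backward filtering
   can undershoot below zero, so envelopes are clipped at 0.
2. **Segmentation** (`detect_cycles`): the tibial accelerometer is low-passed
   at 60 Hz; heel-strike impacts are local maxima above
   median + 3·(MAD-based SD), pruned in two passes so that no two impacts are
   closer than half the median provisional inter-impact interval. A cycle is
   the half-open span between consecutive impacts. Segmentation from known
   boundaries (synthetic data) is available via `use_true_boundaries`.
3. **Time normalization** (`time_normalize`): each cycle is linearly
   interpolated onto 200 points spanning 0–100% of the cycle. Linear
   interpolation was chosen over splines because it is exactly testable
   (ramps map to ramps, 200-point input is a fixed point) and the 200-point
   grid oversamples a 10 Hz envelope generously.
4. **Data structures** (`single_cycles`, `averaged_cycles`,
   `concatenated_cycles`): the factorization inputs built from $k$
   consecutive cycles — each single cycle (SNG), their pointwise mean (AVR),
   or their temporal concatenation (CNC). Peak normalization (each muscle
   scaled to a maximum of 1) is applied *within each constructed structure*,
   which is how per-channel amplitude normalization composes naturally with
   each analysis; normalizing once per recording instead is possible by
   constructing structures from a pre-normalized set, and the block-mean
   equivalence between CNC and AVR (tested) is unaffected because the two
   normalizations differ only by row scaling.

## Dimensionality selection

`select_dimensionality` runs NMF for $N = 1 \ldots n_{max}$ and picks the
smallest $N$ that (a) reaches a VAF of at least 0.90 and (b) sits past the
elbow of the curve, operationalized as a VAF gain from $N$ to $N+1$ below
0.05. Both thresholds are arguments. When no $N$ satisfies both, the function
returns $n_{max}$ and flags the result rather than failing — a real curve
with no elbow is information, not an error.

Random-factor baselines (`random_baseline`) quantify how much VAF random
variability alone achieves: one extracted factor is paired with a random
counterpart, either used as drawn (scaled to the data's mean amplitude) or
refined by exactly 1000 multiplicative updates with the extracted factor
held fixed. Both readings of "free to vary" are implemented because they
answer different questions: the unoptimized baseline measures chance-level
reconstruction (~30–36% VAF on the default cohort), while the optimized one
solves a convex fixed-factor problem and necessarily climbs back to
near-optimal VAF. We take no position on which was intended historically;
the `optimize` flag chooses.

## Module matching and averaging

Two module sets are compared by the normalized scalar product between best
matched pairs (`match_modules`): the bijection maximizing total similarity,
found by exhaustive enumeration (module counts here are ≤ 7, so the
assignment problem is tiny and the global optimum is guaranteed — greedy
matching is order-dependent). Single-cycle factorizations of a subject are
summarized by aligning each to a reference factorization (the full
concatenation) by weighting-based matching and averaging the aligned factors
(`average_matched_factorizations`). Matching for alignment uses weightings,
not activations, because weightings are the quantity compared across
structures throughout.

Intra-structure repeatability is reported as the mean over all pairwise
comparisons across cycle counts (or cycle pairs for SNG). Activation-signal
similarities are only computed where activation vectors share a common grid
(SNG and AVR, both 200 points); concatenated activations of different $k$
have different lengths and are not comparable pointwise.

## The synthetic generator

The raw 12-subject treadmill EMG this analysis family is typically applied
to is not publicly available, so the package ships a generative counterpart
(`generate_subject`) whose structure matches the model the analysis assumes:

* **Ground truth** (`default_ground_truth`): 10 muscles, 5 modules — weight
  acceptance (VL/VM + GX, burst at 10% cycle), propulsion (SO/GL/GM, 40%),
  swing (TA/RF, 82%), leg deceleration (BF/ST, 96%, wrapping the cycle
  boundary), and a transition module (ankle muscles + RF, GX-dominant) with
  small bursts at 2%, 63% and 97%. Activation templates are sums of
  circularly wrapped Gaussians on the 200-point grid. The module energies
  are balanced so that the structure is genuinely five-dimensional: the
  noiseless VAF curve is 0.49 / 0.69 / 0.82 / 0.93 / 1.00 for
  $N = 1 \ldots 5$, and a 4-module fit leaves one muscle (GX) poorly
  reconstructed — the qualitative signature reported for real walking EMG,
  where a diffuse fifth module is needed to finish reconstructing TA, RF
  and GX.
* **Step-to-step variability**: per-cycle, per-module lognormal amplitude
  gains (CV 0.10), Gaussian jitter of burst centers (SD 2% of cycle),
  additive envelope noise truncated at zero (SD 5% of each channel's peak),
  and lognormal cycle durations (mean 1.1 s, CV 0.03 — 40 cycles fit a 60 s
  treadmill window at natural cadence). Lognormal amplitude noise keeps
  envelopes positive; truncation of the additive term preserves
  nonnegativity. These defaults are the package's committed study
  conditions; calibration tests verify the realized dispersions match the
  configured ones.
* **Raw synthesis** (`synthesize_raw`): envelopes are resampled to each
  cycle's duration at 2000 Hz and multiplied by a zero-mean, unit-variance
  Gaussian carrier band-limited to 20–500 Hz, then passed through a
  10–500 Hz acquisition filter. The spectral fine structure of surface EMG
  beyond its bandwidth is deliberately not modeled. The accelerometer
  channel is a gait-locked low-frequency sway (two periods per cycle) plus
  small sensor noise, with one damped 15 Hz cosine impact (amplitude 10×
  baseline SD, 20 ms decay) at each cycle start and a terminal impact
  closing the last cycle. The impact peaks at onset so the detected maximum
  falls on the cycle boundary; the sway's bounded amplitude keeps the
  adaptive MAD threshold crossing only at impacts, giving the detector
  perfect recall and precision on clean synthetic data.

What passing tests on this generator do show: the pipeline recovers known
weightings, activation timings, dimensionality and variability parameters
from data with the assumed structure, through the full raw-signal path.
What they do not show: robustness to electrode artifacts, crosstalk,
non-stationary fatigue drift, bilateral coordination, or module structures
that violate the generative model — real-data claims need real data.

## The cohort study

`run_cohort` generates 12 subjects and emits tidy tables for the three
experiments: VAF by data structure and cycle count, intra-/cross-structure
module similarity, and fixed-weightings cross-reconstruction (weightings
from first-half structures, cycles 1–20, applied to second-half and
full-record concatenations). Cross-reconstruction is reported under two
rules: `free` re-optimizes activations under the fixed donor weightings (a
convex problem — forgiving by construction, VAF ≈ 0.99 for any sensible
donor on the default cohort), and `original` combines donor weightings with
the target's own extracted activations after module matching, with no
re-optimization — the discriminative variant, under which
concatenation-derived weightings outperform average-derived ones. Summaries
are descriptive (means and SDs per condition); the tables carry full
per-subject detail so any inferential test can be run downstream.

Cohort runs use 10 NMF restarts per factorization (standalone `nmf` defaults
to 20); the full 12-subject study is ~600 factorizations and finishes in a
few minutes on one CPU, with best objectives indistinguishable from the
20-restart setting on this data. All randomness flows from one master seed
(subject seeds and per-subject analysis streams are derived offsets), so
reruns are bit-identical.

## Numerical choices

* Multiplicative-update denominators carry an epsilon of 1e-12 against
  division by zero; convergence is declared at a relative objective change
  below 1e-6 or 1000 iterations, whichever comes first (fixed-iteration
  baselines force the literal count with `tol = 0`).
* Restart ties are broken by the earliest restart (strict improvement
  required), making best-of-restarts deterministic under a fixed RNG stream.
* Max-normalization guards all-zero columns (left unscaled) and
  `peak_normalize` leaves all-zero channels unchanged with a warning rather
  than dividing by zero.
* `vaf` errors on all-zero data ("degenerate data") instead of returning
  NaN; per-muscle VAF is `NA` for an all-zero muscle row.

## Worked example

```{r example, eval = FALSE}
rec <- generate_subject(simulation_config(seed = 42))
set <- preprocess_recording(rec)

cnc <- concatenated_cycles(set, 40)
fit <- nmf(cnc, n_modules = 5, seed = 1)
fit$vaf_overall          # ~0.993

sel <- select_dimensionality(cnc, n_max = 8, restarts = 10, seed = 1)
sel$n                    # 5

match_modules(fit$S, rec$ground_truth$weightings)$similarities
# ~0.99 1.00 0.96 0.98 0.99 — extracted modules recover the ground truth
```

## Known limitations

* Exact NMF is not unique on data whose modules overlap in muscles or time:
  on zero-variability synthetic data every structure is reconstructed
  perfectly (VAF ≈ 1), yet independently initialized fits can return factor
  pairs that differ by an exact re-mixing. Repeatability of the *factors* is
  therefore bounded by the identifiability of the data, not by the
  optimizer, and similarity between repeated fits of identical data
  plateaus near — but not at — 1.
* The generator emulates one leg, one walking speed, and stationary
  statistics; fatigue, speed changes and pathology are out of scope.
* Exhaustive module matching is exact but limited to ≤ 7 modules; larger
  sets would need a polynomial assignment solver.
* The elbow operationalization (ΔVAF < 0.05 with a 0.90 floor) is one of
  several defensible ways to formalize the visual change-of-slope heuristic
  used in this literature; both thresholds are exposed as arguments so
  alternatives can be evaluated.
* Reported cohort numbers characterize the synthetic study conditions, not
  any real cohort.
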