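---
title: "Quantifying cross-session reactivation of neuronal ensembles from calcium traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-session reactivation of neuronal ensembles from calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caensembles)
```

## The problem

Miniature head-mounted microscopes record the activity of dozens to hundreds
of hippocampal CA1 neurons in freely moving mice across repeated behavioral
sessions (context exploration, rest, re-exposure a day later), via the
fluorescence of a genetically encoded calcium indicator sampled at 20
frames/s. A central question for memory research is whether the *ensembles*
— subsets of neurons that fire synchronously — observed while an animal
explores a context *reactivate* in later sessions, since reactivation
shortly after learning is thought to drive consolidation, and manipulations
such as general anesthesia may suppress it.

`caensembles` implements the trace-level half of that analysis as a tested,
reusable pipeline. It deliberately starts from per-session fluorescence
trace matrices (frames × neurons, with neuron identity consistent across
sessions): movie-level processing — motion correction, spatial filtering,
and cell identification from pixels (e.g. CNMF-E) — is mature, tool-specific
territory and is out of scope here.

## The pipeline

### Preprocessing

1. **ΔF/F** (`compute_dff()`): per neuron,
   $\Delta F(t)/F_0 = (F(t) - F_0)/F_0$ with $F_0$ the neuron's mean
   fluorescence over the whole session. Invariant to positive rescaling of
   a neuron's raw trace, so the arbitrary brightness scale cancels.
2. **Event detection** (`detect_events()`): a calcium event must exceed both
   an absolute threshold (0.01 a.u.) and 3 per-neuron session standard
   deviations. The published rule states thresholds but not what one "event"
   is; we count *rising edges* of the joint threshold with a 10-frame
   (0.5 s) refractory period, so a burst with ripples counts once — the
   closest automatic analogue of counting transients by eye. The SD is
   per neuron (amplitudes vary several-fold between cells), over the entire
   session.
3. **High-pass filtering** (`highpass_filter()`): 4th-order Butterworth,
   0.01 Hz cutoff, applied forward and backward per neuron (zero phase, so
   event times do not shift relative to ground truth). The per-neuron mean
   is removed first; this rejects DC exactly and keeps the IIR edge
   transients small on finite sessions.
4. **Rectified z-score** (`zscore_rectify()`): per neuron, subtract the
   session mean, divide by the session SD, and clip negative values to
   zero. Non-negativity is what makes the factorization below well posed.
   A zero-SD neuron becomes an all-zero column (with a message), not an
   error.
5. **Binning** (`bin_traces()`): mean over consecutive 4-frame windows
   (200 ms at 20 Hz), the trailing partial bin dropped. Mean rather than
   sum keeps values on the z-score scale whatever the bin size; sum is
   available via `agg = "sum"` (for this factorization the two differ only
   by a global scale).

### Ensemble extraction

The binned activity matrix $X$ (bins × neurons) is factorized as
$X \approx W H$ with $W \ge 0$ the *occurrence* matrix (bins × ensembles)
and $H \ge 0$ the *pattern* matrix (ensembles × neurons), minimizing the
squared-Frobenius cost $\|X - WH\|_F^2$. The published description leaves
the cost expression unrendered; squared Frobenius error is the standard NMF
objective consistent with the cited methodology and is recorded here as a
design decision.

* **Updates**: multiplicative (Lee–Seung) updates, which preserve
  non-negativity and never increase the cost; a guard of $10^{-12}$ in the
  denominators avoids division by zero. The per-iteration cost trace of the
  winning run is stored so monotonicity is checkable after the fact.
* **Restarts**: NMF is non-convex, so each factorization is repeated from
  `n_restarts` seeded random initializations (production default 1000,
  matching the multi-start protocol; the validation suites use 10–50,
  which at their problem sizes reach the same optima) and the lowest-cost
  restart wins.
* **Convergence**: a restart stops when the relative cost change drops
  below $10^{-6}$ or after 500 iterations.
* **Normalization**: pattern rows are L2-normalized with the norms folded
  into the occurrence columns, which leaves $WH$ unchanged (asserted to
  $10^{-10}$) and makes patterns directly comparable by cosine.

**Model order (AICc)** (`select_rank_aicc()`): for each candidate rank $r$,
the best-of-restarts residual sum of squares $RSS_r$ is scored with the
small-sample-corrected Akaike criterion
$$\mathrm{AICc}(r) = n\,\ln(RSS_r/n) + 2k + \frac{2k(k+1)}{n-k-1},$$
with $n = n_\mathrm{bins} \times n_\mathrm{neurons}$ observations and
$k = r\,(n_\mathrm{bins} + n_\mathrm{neurons})$ free parameters under a
Gaussian residual likelihood. The published method names AICc but not $n$
or $k$; this accounting is the natural one for the factorization and is
echoed into every output so alternatives can be audited. Ties break toward
the smaller rank; ranks with $n - k - 1 \le 0$ are excluded.

### Matching and reactivation

Ensemble patterns from two sessions X and Y (identical neuron ordering,
validated) are compared by the normalized dot product; for non-negative
patterns the cosine lies in $[0, 1]$. The **matching score**
$$\mathrm{MS}(X,Y) = \frac{1}{N_X}\sum_{i=1}^{N_X}
\Theta\Big(\max_j \tfrac{p_i \cdot q_j}{\|p_i\|\,\|q_j\|} - c\Big)$$
is the fraction of X's patterns whose best partner in Y strictly exceeds
the threshold $c = 0.6$ (the published operating point). The inequality is
strict: a cosine of exactly $c$ does not match. MS is asymmetric by
construction. All-zero patterns (removed during extraction, handled
defensively here) have cosine 0 and can never match.

The **three-session analysis** (`reactivation_analysis()`) partitions the
Day 1 context ensembles by whether they reactivate in the rest session,
and reports, within each partition, the percentage that also reactivates
in the Day 2 context session. Day 1 patterns are matched *independently*
against rest and against Day 2 — no transitivity is assumed. An empty
partition gives `NA` ("undefined"), never 0.

## The synthetic-data generator

Raw data behind the motivating experiments are not public, so validation
rests on simulation with planted ground truth (`generate_ensembles()`,
`generate_session()`, `generate_session_pair()`,
`generate_session_triplet()`). A session is

> baseline + slow sinusoidal drift + ensemble transients + background
> transients + Gaussian noise,

with every source seeded from one generator per call (the caller's RNG
state is untouched).

| parameter | default | why |
|---|---|---|
| `frame_rate` | 20 Hz | miniscope acquisition rate of the motivating experiments |
| `decay_tau` | 0.5 s | fast-indicator decay; `rise_frames = 2` (100 ms rise) |
| `event_rate` | 0.1 /s | sparse ensemble activations, ~1 per 10 s |
| `amp_jitter_sigma` | 0.2 | lognormal per-event amplitude jitter, so NMF weights are identifiable but not binary |
| `drift_freq` | 0.002 Hz | below the 0.005 Hz bound, exercises the 0.01 Hz high-pass |
| `drift_amplitude` | 0.1 | 10% of baseline, typical slow photobleaching/refocus drift |
| `background_rate` | 0.02 /s | independent per-neuron transients: realistic clutter for the factorization |
| `noise_sd` | 0.05 | shot/sensor noise at ~5% of baseline |
| `max_overlap` | 0.25 | pairwise cosine cap between planted membership patterns |

The amplitude scale is exposed (`amplitude`, `baseline`) rather than fixed,
because "arbitrary units" are exactly that; ΔF/F cancels it.

What the generator does *not* emulate: pixel-level artifacts and motion,
spike-to-calcium nonlinearity (transients superpose linearly here),
non-stationary firing rates, and cell-registration errors across sessions
(neuron identity is perfect by construction). Passing recovery tests
therefore demonstrate correctness of the *analysis*, not robustness to
imperfect upstream cell registration.

## Validation studies and their design

The test suite and `scripts/acceptance.R` recompute these from scratch:

* **Oracle equivalence** — on 1000 random small pattern sets, the
  vectorized matching score equals an independently coded brute-force
  double loop exactly, and the MS identities (bounds, self-match = 1,
  monotone in $c$, scale invariance) hold.
* **Exact factorization** — exact low-rank non-negative matrices (rank ≤ 5)
  are reconstructed with relative error < $10^{-3}$, with non-increasing
  cost traces.
* **Rank and pattern recovery** — 20 seeded sessions, each 180 s with 3
  *disjoint* 6-neuron ensembles over 18 neurons, activation rate 0.2/s,
  noise SD 0.05 (event SNR ≈ 15), no background transients; 50 restarts,
  candidate ranks 1–6. AICc must pick rank 3 in ≥ 90% of replicates and
  planted-vs-recovered best-match cosines must average ≥ 0.9.

  The design of this study deserves a note. With overlapping memberships or
  background clutter, the rectified-z-score pipeline gives the data *real*
  additional weak components — the between-event noise floor (rectified
  noise has positive mean) and event-offset terms that overlapping
  memberships cannot absorb — and AICc, correctly, counts them: the chosen
  rank then exceeds the planted ensemble count even though every planted
  pattern is still recovered (a separate test asserts exactly that under
  clutter). A model-order validation must therefore plant *only* the
  structure it asks the criterion to count: disjoint memberships covering
  all neurons, activation mass well above the noise (so the rectified floor
  vanishes), and no background firing. This is a property of
  rectified-then-factorized pipelines generally, not of this
  implementation.
* **Shared-fraction recovery** — 20 seeded session pairs, 10 disjoint
  4-neuron ensembles over 60 neurons, planted shared fraction 0.5;
  extraction at ranks 8–12 with 10 restarts, then MS(Day 1, Day 2). The
  run mean must land within ±0.15 of 0.5. Session-unique ensembles leave
  their partner session's neurons silent, so extraction may add a noise
  component there; this inflates $N_X$ slightly and biases MS a little
  below the planted fraction — visible, tolerated, and documented.
* **Group-difference echo** — 4 simulated "high-sharing" animals (shared
  fraction 0.30) versus 4 "low-sharing" animals (0.10), each animal with
  its own ensemble count (9–12, as ensemble counts vary between real
  mice; 3-neuron ensembles over 72 neurons, extraction at ranks 7–14):
  the group means must order correctly with a two-sided Welch test at
  $p < 0.05$. This is a *qualitative* echo of the in-vivo contrast
  between control and anesthetized groups; the printed group values of
  the motivating study derive from non-public raw data and are not
  reproduction targets.
* **Preprocessing and events** — DC input maps to zero; 0.001 Hz drift is
  attenuated > 90% while 1 Hz content is preserved within 5% (measured
  mid-signal, away from filter edges); ΔF/F and z-score/rectify match
  two-line oracles elementwise; planted transient counts are recovered
  exactly; sub-0.01 a.u. transients count zero; counts are monotone in the
  SD multiplier.
* **Reactivation** — the planted 6/3/2 design (6 Day 1 ensembles, 3 recur
  in rest, 2 of those recur on Day 2) returns 66.7% vs 0% exactly,
  agreeing with brute-force counting.

Problem sizes (sessions of 120–180 s, 18–76 neurons, 10–50 restarts) are
chosen so the whole validation battery runs in minutes on one CPU while
leaving the statistics (Poisson counts, recovery rates) well resolved.

## Numerical choices and degenerate inputs

* Cosines are clamped to $[0, 1]$ after the matrix product, so downstream
  bound assertions are exact under floating-point round-off.
* `RSS` is floored at $10^{-300}$ inside AICc to keep the log finite on
  numerically exact factorizations.
* All-zero activity matrices are an error naming the session; all-zero
  pattern rows are removed with occurrences adjusted; zero-variance neurons
  are messages, not errors, and become zero columns/zero counts.
* One run seed deterministically derives per-stage seeds by stage-name
  hashing, so any stage can be re-run in isolation and a full
  `run_pipeline()` report (timings excluded) is bit-reproducible — see
  `report_hash()`.

## Known limitations

* The AICc parameter accounting ($k = r(n_\mathrm{bins} +
  n_\mathrm{neurons})$) treats every factor entry as free; with heavy
  regularity (sparse patterns) it may over-penalize large ranks on small
  sessions, and — as discussed above — on rectified data it will count
  genuine noise-floor structure as components when present.
* The matching score depends on the extracted ensemble count of the
  *query* session; extra (noise) components dilute it. Comparisons across
  groups should therefore use identical extraction settings, as
  `run_pipeline()` enforces.
* Trace non-stationarities other than the modeled slow drift (e.g. abrupt
  focus shifts) are not simulated and may require additional upstream
  correction on real data.
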