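---
title: "Closed-loop SWR blockade and CA1 place-code stability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop SWR blockade and CA1 place-code stability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrpipe)
```

## The question and the design

Hippocampal sharp wave/ripple (SWR) events — a negative sharp-wave
deflection in CA1 stratum radiatum coinciding with a 150–200 Hz ripple
oscillation in stratum pyramidale — are the moments when place-cell
ensembles replay recently experienced trajectories, and they are widely
held to drive consolidation. The experimental design this package analyses
asks whether SWRs in the sleep between two exposures to the same novel
environment are needed to *stabilise* the newly formed CA1 spatial map. A
closed-loop detector senses each ripple online and triggers a 200 ms
inhibitory light pulse over CA1 pyramidal cells; on control days the same
pulses are delivered 1.32 s late, so they miss the triggering event while
depositing the same light energy. Stability of the code is then read out
from the two flanking exploration sessions.

The experimental day is: pre-sleep, first 24 min exploration, 3 h of
sleep/rest with closed-loop stimulation (the first 20 min of each hour
recorded), second 24 min exploration, post-sleep, and a final 30 min rest
with regular half-intensity 500 ms pulses every 3 s used to quantify each
cell's inhibition. `simulate_day()` reproduces this timeline;
`day_config()` exposes every duration so analyses can run at reduced scale.

## The synthetic-data generator

Real recordings for this paradigm are not publicly deposited, so the
package ships a generator that produces every input the analysis consumes,
with known ground truth. What it emulates, and what it deliberately does
not, determines what passing tests mean.

**Trajectories.** A mean-reverting (Ornstein–Uhlenbeck) velocity process
with reflective walls, sampled at 40 Hz. The per-component stationary
velocity s.d. is set so the 2-D speed has the requested mean (default
12 cm/s, `tau` = 0.7 s). Arena sizes and running-speed statistics are not
reported for the original experiment; the defaults (60 × 60 cm, 12 cm/s)
are nominal values typical of mouse open-field work, and a 24 min default
session covers over 90% of 2 cm bins, which is what the rate-map analyses
require. Real mouse paths have thigmotaxis, rests and grooming bouts that
this walk lacks.

**Place fields.** One isotropic Gaussian bump per cell (default width
sigma = 6 cm, peak 4–15 Hz over a 0.1 Hz baseline), constant within a
session. Between sessions each cell's centre is displaced by a per-cell
drift distance in a random direction and its peak is scaled log-normally —
`drift = 0` and unit scaling is a perfectly stable code, large drift is
global remapping, and a mixture emulates stable and remapping
subpopulations. Multi-field cells, directionality and theta modulation are
not modelled.

**Spikes.** An inhomogeneous Poisson process with rate
`lambda(t) = baseline + peak * exp(-||x(t) - c||^2 / (2 sigma^2))`, treated
as piecewise-constant over tracker steps (exact for such a rate profile).
Sleep firing is homogeneous Poisson at per-cell rates drawn from
0.5–3 Hz — adequate for the pulse-triggered count statistics, which assume
only exchangeable baselines, but devoid of burstiness and state structure.

**Sleep LFP.** Two channels at 2000 Hz (the original wide-band data were
digitised at 24 kHz; 2000 Hz preserves the ripple band and keeps runtimes
proportionate — the rate is configurable). Background is 1/f-shaped
Gaussian noise with a 20% white floor. Ripples are Gaussian-enveloped
sinusoids at 160 Hz (the predominant frequency of intact events), 7
nominal cycles, with peak amplitude 5× the background's 100–250 Hz band
s.d.; the radiatum channel carries a concurrent negative half-width
Gaussian deflection (the sharp wave), 5× its background s.d. No amplitudes
are reported for the original recordings; these defaults are chosen so
that a 4 s.d. comparator threshold detects essentially all intact events —
i.e. the generator and the default detector are calibrated to each other
the way an experimenter calibrates a potentiometer against their own
signal. Event times are Poisson (default 0.3 Hz) thinned to a minimum
separation of 250 ms plus the event length.

**Blockade emulation.** `truncate_after_cycles = 2` cuts each ripple's
envelope two cycles after the oscillation becomes apparent, defined as the
envelope's half-maximum rise. This mirrors the observed effect of the
closed loop — oscillation destroyed within at most two ripple cycles of
detection — without simulating the light-evoked field response itself,
which is a recording artifact rather than a signal of interest. The cut
point matters: truncating two cycles after the *nominal* Gaussian onset
(2 envelope s.d. before the peak) would leave almost no energy and no
detector, online or offline, could see such events, contradicting both the
physics (the loop fires near the envelope peak, not at the statistical
onset) and the observation that truncated remnants are identifiable
offline.

**Light suppression.** Each spike inside a pulse window is deleted
independently with probability `suppression` (default 0.9 in day
simulations; the inhibition benchmarks use 0.8). An optional rebound adds
Poisson spikes in a 50 ms post-pulse window; it is off by default and is
displayed, not tested, in the analyses.

## The detector emulation

The analog device is emulated as: differential channel (pyramidale −
radiatum), causal Butterworth band-pass with 4 poles total over
100–200 Hz (the device's centre frequency was 150 Hz and its pole count 4;
its bandwidth/Q is unreported, so the band is a configurable bracket of
the ripple range), gain 10, and a comparator at `threshold_sd` (default 4)
times the filtered signal's session s.d. — the physical device used a
potentiometer whose setting is unreported, so threshold units are
standardised to the session. On an upward crossing outside an active TTL a
200 ms TTL is emitted; TTLs cannot retrigger while active and may re-fire
immediately after (matching traces where the detector re-fires directly
after a pulse). The delayed mode shifts laser onsets by exactly 1.32 s —
implemented as an exact time shift, since only the total delay of the
original script loop is specified. Both modes therefore deliver identical
pulse counts and total light duration; this energy parity is asserted in
the tests.

Whether the in-vivo detector was blanked after each pulse beyond the TTL
itself is not stated; this emulation adds no extra refractory period.

The offline detector is deliberately non-stringent: zero-phase band-pass
(100–250 Hz), rectification, a 15 ms moving-average envelope, z-scoring
against the whole session, threshold 2 s.d., events of 15–500 ms with
gaps under 10 ms merged. The 15 ms envelope window (about two ripple
cycles) is chosen so that a two-cycle truncated stub integrates above
threshold long enough to satisfy the minimum duration; with a 10 ms
window such stubs are mostly lost, defeating the detector's purpose of
recovering blocked-event remnants. At 2 s.d. the detector accepts many
noise crossings (precision ~0.5 on synthetic data); that is the intended
trade-off, and the 6 s.d. false-positive check in the tests shows the
envelope statistics themselves are sound.

## Spectral verification

Ripple abolition is demonstrated spectrally, not by counting detections.
`triggered_spectrogram()` tiles 150 ms multi-taper windows (75% overlap)
across ±span around each trigger; `align_shift` subtracts the control
delay from laser onsets so the triggering event sits at time 0, and a test
asserts this is bin-for-bin identical to using the TTL times directly.
`normalized_event_spectrum()` subtracts the mean spectrum 400 ms after
each event from the mean spectrum at the event; on stationary noise the
difference converges to zero (tested at 500 events against the analytic
standard error), and truncation shrinks the 150–200 Hz peak.

Multi-taper parameters are NW = 3 with 5 Slepian tapers on 150 ms windows
— unreported in the original analysis, standard choices, configurable. The
tapers are computed from the symmetric tridiagonal eigenproblem, checked
in the tests for orthonormality and >99.9% in-band energy concentration.
At 2000 Hz and 300-sample windows the frequency resolution is 6.67 Hz and
160 Hz falls exactly on a bin.

## Place maps and stability metrics

Occupancy and rate maps use 2 cm square half-open bins over the arena's
bounding box, a 2.5 cm/s speed filter for explorations, 0.1 s minimum
occupancy, and Gaussian smoothing (sigma = 1 bin) applied to spike counts
and dwell separately before division, which keeps edge bins unbiased.
Spike positions are linearly interpolated between tracker samples. None of
these values are reported in the original; all are field-standard and
configurable, and the conservation tests (dwell sums to session time,
counts sum to spike count) pin the bookkeeping.

Sparsity is the Skaggs form `(sum p*lambda)^2 / sum p*lambda^2` with `p`
the dwell fraction; coherence is the Pearson correlation between each
valid bin's rate and the mean of its available 8-neighbours, computed on
the *unsmoothed* map (the metric's usual convention; a Fisher-z option
exists and is off by default). The exact formulas are cited rather than
restated in the source experiment; the standard definitions are adopted
here and verified against brute-force oracles.

Rate change is `RC = |f1 - f2| / (f1 + f2)` on whole-session mean rates
(speed filter off, matching "average firing rates"); cells silent in both
sessions are excluded as NaN. Map correlation is the Pearson correlation
over bins valid in both sessions' maps (minimum 20 joint bins; zero
variance gives NaN and exclusion).

Cofiring uses 250 ms temporal bins (unreported in the original;
configurable — halving or doubling the bin changes coefficients smoothly
but not the between-condition comparison). Each pair's per-session
coefficient is the Pearson correlation of the two units' binned counts;
the between-session *similarity* is the Pearson correlation of those
coefficients across pairs, and two conditions are compared with Fisher's Z
using the pair counts as n. The phrase "cofiring vectors per cell pair"
admits a second reading (a per-pair binwise product vector correlated
across sessions), but only the scalar-per-pair reading makes the reported
Fisher-Z sample sizes equal the number of cell pairs, so it is the one
implemented. Pairs require both units to fire ≥ 10 spikes in each
exploration; exclusions are recorded on the result.

Whether exploratory SWR epochs were excised from rate computations is not
stated in the source; they are not excised here, and the generator does
not place SWRs in exploration sessions.

## Inhibition statistics

For each cell, spikes are counted inside each 500 ms pulse and in the
500 ms immediately before it (the baseline window definition comes from
the referenced prior method, whose details are not restated; the
immediately-preceding equal-length window is the natural paired choice).
The pairs enter a two-sided Wilcoxon signed-rank test with zero
differences dropped; direction comes from the median non-zero difference.
Alpha is 0.05 per cell with no multiple-testing correction, matching the
reported per-cell significance convention. The test's type-I rate and
power are characterised on generator nulls and suppressed cells
(suppression 0, 0.4, 0.8), and the group statistics (one-way ANOVA,
two-sample KS) are checked against independent sums-of-squares and ECDF
oracles at 1e-10.

## Numerical and engineering choices

* Every generator accepts a seed and restores the caller's RNG state;
  `simulate_day()` derives independent sub-seeds per stream, so whole-day
  reports are bit-identical under the same (config, seed).
* Times are seconds from day start everywhere; sample indices appear only
  at I/O boundaries. File formats are minimal text/binary dialects
  (two-column spike text, `t,x,y` CSV, interleaved little-endian int16
  LFP with a YAML sidecar, `onset,offset,...` CSV for events) rather than
  NWB/NEO containers, to keep the dependency footprint small.
* Degenerate inputs are defined, not accidental: zero-duration
  trajectories are empty, all-zero rate maps have NaN sparsity, all-tied
  pulse counts give an "unchanged" classification with a logged note,
  zero-variance maps or count vectors are excluded with NaN.
* The day-exclusion rule of the original protocol (more than 5 min of
  continuous movement in the middle sleep) is computable only when
  tracking covers sleep; the generator does not track sleep sessions, so
  the rule is not applied to synthetic days.

## Problem sizes used in tests and scripts

The shipped analyses run at reduced scale chosen as the smallest sizes at
which every statistic is well-conditioned: mini days with 10-min
explorations, 1–2 two-minute sleep blocks and 10–25 cells for the
end-to-end checks; 10 min of sleep LFP for spectral recovery; 30 min of
pulsed rest and 50–200 cells for the inhibition benchmarks; 24-min
explorations with 40–50 cells for drift-monotonicity and zero-drift
recovery. The full-scale defaults of `day_config()` reproduce the
original timeline and run in a few minutes per day.

## Known limitations

* The generator's sleep LFP has no state structure (no slow oscillation,
  spindles or theta), so detector performance on it bounds only the
  ripple-vs-stationary-background problem, not staging errors.
* Place-field drift is the only remapping mechanism; field appearance /
  disappearance and rate-only remapping arise as limiting cases (large
  drift, pure rate scaling) rather than as distinct processes.
* The light-evoked field response seen on real traces is not synthesised;
  analyses that would have to reject that artifact are untested against
  it.
* Interneurons are not simulated and the per-cell inhibition statistics
  are validated for pyramidal-like Poisson units only.
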