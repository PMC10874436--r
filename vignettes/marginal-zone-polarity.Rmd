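---
title: "Modelling and measuring long-range polarity in the marginal zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring long-range polarity in the marginal zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzring)
```

## The biological problem

Before gastrulation, a chick embryo is a flat disc roughly 3 mm across, yet
it reliably forms a single primitive streak at its posterior edge. Signals
that suppress additional streaks must therefore act over distances far
beyond the reach of a diffusing morphogen, and they must act fast: when the
posterior half of an embryo is removed, the anterior fragment repolarises
within about five hours, implying a signal travelling along the
extraembryonic marginal zone (MZ) at more than a cell length per minute
(`mz_transit_speed()` reproduces this arithmetic). Calcium transients
propagating between MZ cells through gap junctions are a candidate carrier:
they are cheap to transmit, fast, and their *activity* (firing amplitude
and participation) can form a spatial gradient even when calcium
concentration itself does not.

`mzring` implements two complementary layers around this idea:

1. a deterministic reaction–diffusion model of BMP4, cVG1/GDF3 and calcium
   activity on a ring of 100 MZ cells, with an irreversible streak-identity
   latch, and
2. the calcium-imaging measurement chain — ΔF/F0 normalisation, baseline
   removal, transient detection, linear-assignment track linking, sector
   histograms — exercised end-to-end on seeded synthetic data with known
   ground truth.

## The ring model

Each cell `i` carries BMP4 `B_i` (streak inhibitor), cVG1 `V_i` (streak
inducer), calcium activity `C_i`, and a binary streak identity `A_i`:

$$\frac{dB_i}{dt} = k_B\,H(C_i-\alpha) - (\gamma_0 + \gamma_C C_i + \gamma_V V_i)\,B_i$$
$$\frac{dC_i}{dt} = k_C A_i + \frac{D}{\Delta x^2}(C_{i+1}+C_{i-1}-2C_i) - \lambda C_i$$
$$\frac{dV_i}{dt} = k_V\,H(\beta_V-B_i) - \mu V_i, \qquad \beta_V > \beta_C$$

with `H` the Heaviside step (defined so that `H(0) = 1`) or, in the
`"hill"` variant, Hill functions with coefficient 4 replacing both
production switches. `A_i` latches to 1 the first time `B_i` falls to
`beta_C` and never releases. The assumptions encoded are: cVG1 and calcium
activity accelerate BMP4 decay; calcium activity above a very low threshold
`alpha` sustains BMP4 production; cVG1 is induced where BMP4 is below
`beta_V`; committed cells are calcium sources; and calcium activity —
unlike the secreted proteins — is transmitted rapidly between neighbours
(the discrete diffusion term).

The initial condition is a shallow linear BMP4 gradient anchored at 1.1 on
the two cells flanking the posterior pole and 2.2 at the anterior pole,
with zero calcium, cVG1 and streak identity. Interpolation is linear in
arc distance between cell centres, which pins those four anchor values
exactly.

### What the scenarios show

In the **intact** scenario, posterior BMP4 decays first (it starts below
`beta_V`, so cVG1 accelerates its decay), the posterior-most cells commit,
and their calcium output both suppresses BMP4 posteriorly and sustains it
anteriorly — a single arc of committed cells centred on the posterior pole,
a posterior-high calcium gradient, and an anterior-high BMP4 gradient.

In the **anterior-half** scenario the committed arc is removed at `t = 0`
together with a 20-cell arc through the pole, slightly obliquely (the
removed arc is shifted by `obliquity_offset` cells, default +2, so the
right edge of the fragment sits closer to the old pole and carries less
BMP4). Calcium activity decays, BMP4 production shuts off, BMP4 falls at
both wound edges, cVG1 rises at **both** edges — the transient bilateral
induction seen in cut embryos — and the right edge, being slightly ahead,
commits first. Its calcium output crosses the fragment and rescues BMP4
production at the left edge before that edge commits: one streak, on the
posterior-leaning side, for either production-switch variant and either
sign of the offset.

### The reference parameter set

The defaults of `mz_params()` are this package's own calibration; the
published model's parameter table is distributed with its supplementary
material rather than in the article body, so a self-contained set is
shipped and users wishing to reproduce the published timings should
override the defaults with the published values. The calibration was
chosen so that (a) at cut time the BMP4 field straddles `beta_V` (above it
anteriorly, below posteriorly), (b) both scenario phenotypes above hold for
both switch variants and mirrored obliquity, and (c) the anterior-half
fragment shows a genuine bilateral cVG1 transient rather than a trivial
one-sided race. The shipped values are

| symbol | value | units | role |
|---|---|---|---|
| `k_B` | 2 | conc/h | BMP4 production |
| `alpha` | 0.001 | activity | calcium threshold for BMP4 production |
| `gamma0` | 0.4 | 1/h | basal BMP4 decay |
| `gamma_C` | 2 | 1/(activity h) | calcium-driven BMP4 decay |
| `gamma_V` | 0.5 | 1/(conc h) | cVG1-driven BMP4 decay |
| `k_C` | 100 | activity/h | calcium source in streak cells |
| `D` | 8000 | cell²/h | gap-junctional transmission |
| `lambda` | 6 | 1/h | calcium decay |
| `k_V` | 2, `mu` = 2 | conc/h, 1/h | cVG1 production/decay |
| `beta_C` | 1, `beta_V` = 1.4 | conc | commitment / induction thresholds |
| `dt` | 5e-5 | h | Euler step |

Two consequences of this calibration are worth stating plainly. First, the
published scheme's step of 1e-4 h would violate the explicit-scheme
stability bound `dt <= dx²/(2D)` at `D = 8000`, so the default step is
5e-5 h; with the published parameter table, set `dt = 1e-4`. Second, with
these values the intact-phase commitment happens 0.20 h after simulation
start (2.80 h before the cut under the default 3 h pre-cut phase) and the
post-cut calcium surge at 2.03 h — the same ordering of events as the
published run, at the timescales this parameter set produces.

**Known limitation.** The oblique bias resolves reliably for offsets of
two cells or more (either switch variant) and for one cell under the Hill
variant, but a one-cell offset under pure Heaviside switches can deadlock
into bilateral commitment: the 2-cell difference in edge BMP4 is compressed
during the post-cut relaxation to less than the time calcium needs to cross
the 80-cell fragment. Near-symmetric cuts are genuinely marginal in this
model class; treat single-cell offsets as outside the reference set's
guaranteed regime.

### Numerical choices

Forward Euler exactly as specified; any negative concentration produced by
discretisation error is clamped to zero and counted
(`final$clamp_count` — zero in all shipped runs). The threshold boundaries
are inclusive on the "on" side (`H(0) = 1`, commitment at `B == beta_C`),
matching the model's piecewise definitions. On a cut fragment the missing
neighbour is mirrored (no-flux): gap-junctional transmission cannot cross
a wound. Instability (non-finite values) aborts with the offending step
rather than propagating NaNs. Convergence is first order (measured order
≈ 1.0 against a 100-fold finer reference), the periodic transmission term
conserves total activity to rounding error, and an unbiased (offset-0) cut
preserves mirror symmetry to < 1e-8, all verified in the test suite.

## The measurement chain

### Traces

`compute_dff()` converts raw per-frame intensities to `100·(F−F0)/F0` with
`F0` the temporal mean — the scale everything downstream uses.
`als_baseline()` implements asymmetric least squares with the protocol's
settings (asymmetry 0.001, roughness penalty 10⁴ — "smoothing factor 4" is
read as the base-10 exponent, the convention of the originating software —
10 iterations, convergence threshold 0.02 on the fraction of changed
weights). Points above the running baseline are down-weighted to 0.001, so
the curve tracks the drifting floor underneath positive transients.

`detect_spikes()` is organised around the protocol's peak-finder settings
(smoothing window 20 frames, local maxima over 5 points, 10% height
filter), with two documented adaptations for raw noisy traces (the
original pipeline ran on matrix-factorised, largely denoised traces):

* the 20-frame moving average serves as a *region* detector; individual
  transients are then resolved inside each region on a 5-point smoothed
  copy, because a 15 s transient spans only ~5 frames at 3 s/frame and the
  20-frame window would fuse any pair closer than ~60 s;
* a noise floor of 4 robust standard deviations (estimated from first
  differences, applied at the matching smoothing scale) supplements the
  10% height filter, which on its own admits smoothed noise maxima once
  the signal-to-noise ratio drops to the stated validity edge of 5.

Amplitude and FWHM are measured on the unsmoothed detrended trace, heights
from the noise floor (lower quartile + 0.6745σ; decay tails occupy too many
frames at 5 mHz for the median to be a safe zero), FWHM by linear
interpolation at half height with a one-sample hysteresis so a single noisy
dip does not truncate the width. Spikes whose half-height support leaves
the recording report `NA` widths.

### Tracks

`link_events()` reconstructs intercellular firing chains with the stated
linking rules: optimal frame-to-frame assignment (a hand-written, fully
tested Jonker–Volgenant solver) under a 90 µm cutoff with squared-distance
costs and non-link alternatives priced at 1.05× the largest accepted cost;
gap closing joins fragment ends to starts within 90 µm and 2 frames;
"splitting" is recorded as an annotation (`split_from`) on the branch
track rather than by duplicating events, so every event belongs to exactly
one track. Track direction is classified into the four half-open quadrants
[0°, 90°), …, [270°, 360°); zero-displacement tracks are unclassified.
`count_active_cells()` counts distinct firing positions by single-linkage
clustering at one blob diameter (13 µm).

`sector_histogram()` divides the marginal-zone annulus arc into four
equal-arc sectors from the cut edge (s1–s4), histograms the
temporal-average image per sector, fits a scaled log-normal by nonlinear
least squares, and reports pixels above the intensity threshold (default
6) plus the fitted peak centre `exp(meanlog − sdlog²)` — the two summaries
used to quantify the spatial activity gradient. Fits on degenerate sectors
(fewer than four occupied bins) are reported as failed rather than
guessed.

## The synthetic-data generators

`make_traces()` draws per-cell spike trains as a refractory renewal
process: intervals are a hard floor (two FWHM, 30 s by default — the
indicator's return to baseline) plus an exponential whose mean is set so
the long-run rate equals the configured 5 mHz; the first spike comes from
the stationary forward-recurrence distribution, making the expected count
exactly rate × duration. Each spike renders as a fast-rise/exponential-
decay transient matched to the 15 s FWHM (a symmetric Gaussian is
available), on the frame grid, plus optional sinusoidal drift and Gaussian
noise. `make_event_field()` places cells on the mid-annulus circle
(inner/outer radii 1500/1620 µm — a ~120 µm wide zone — spacing 12 µm),
draws track initiations from a linear rate ramp along the arc, and
propagates each track to a uniformly random neighbour within the step
radius for a geometric number of events; `min_separation_um` optionally
rejects tracks that would come within the linking cutoff of a concurrent
track, the regime in which linking is provably unambiguous.
`render_movie()` turns events into Gaussian blobs on a Gaussian or
log-normal background and emits the temporal average for sector analysis.

What the generators deliberately do **not** emulate: photobleaching,
shot-noise statistics, cell movement (the real pipeline ran motion
correction first), overlapping cells, or empirically calibrated amplitude
and track-length distributions (not published numerically; the defaults
are labelled placeholders). Passing round-trip tests therefore demonstrate
that the analysis chain is correct and unbiased *under its stated
assumptions*, not that it is robust to every artefact of real recordings.

## Scoring conventions in the tests

Detection is scored by matching calls to true spikes within one generating
FWHM (15 s): at the stated validity edge (amplitude/noise = 5) the argmax
of a sharp noisy transient jitters by 2–3 frames, so a matching window of
the transient's own width is the appropriate benchmarking convention.
Recall and precision are required to reach 0.95 under the stated regime
(amplitude/noise ≥ 5, inter-spike interval ≥ 2 FWHM); pooled frequency
must sit within two standard errors of 5 mHz; FWHM recovery within one
frame. Track recovery must be exact when concurrent tracks stay > 90 µm
apart, and log-normal sector-fit parameters must come back within 5% on
sectors of ≥ 10⁴ pixels. Problem sizes in the default test run — 100–150
traces of 200 frames, event fields of a few hundred tracks, four scenario
pairs of ring-model runs — were chosen as the smallest sizes at which
these statistical criteria are stable.

## Reproducing the analyses

The `analysis/` scripts run the three analyses end-to-end and write their
tables under `results/`: `01_ring_model.R` (both scenarios, both switch
variants), `02_calcium_traces.R` (trace generation, detection, scoring),
`03_tracks_and_sectors.R` (event field, linking, angles, active cells,
sector histograms). `scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes every headline quantity from scratch against the installed
package.
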