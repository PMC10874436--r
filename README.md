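# mzring

How does a 3 mm chick embryo make exactly **one** primitive streak? A
diffusing morphogen cannot carry positional information across hundreds of
cell diameters within the few hours an isolated anterior half-embryo needs
to repolarise — the signal must travel along the extraembryonic marginal
zone (MZ) at more than a cell length per minute. `mzring` implements a
candidate mechanism and the measurements that support it:

* **Ring model.** A deterministic reaction–diffusion model of the MZ as a
  ring of 100 cells, each carrying BMP4 (streak inhibitor, `B`), cVG1/GDF3
  (streak inducer, `V`), gap-junction-transmitted calcium activity (`C`)
  and an irreversible streak-identity latch (`A`):

  $$\dot B_i = k_B H(C_i-\alpha) - (\gamma_0+\gamma_C C_i+\gamma_V V_i)B_i$$
  $$\dot C_i = k_C A_i + \tfrac{D}{\Delta x^2}(C_{i+1}+C_{i-1}-2C_i) - \lambda C_i$$
  $$\dot V_i = k_V H(\beta_V-B_i) - \mu V_i,\qquad \beta_V>\beta_C,\ H(0)=1$$

  solved by forward Euler, with Heaviside or Hill (n = 4) production
  switches, an intact scenario and an oblique anterior-half-cut scenario.

* **Calcium-imaging analysis.** 100×ΔF/F0 normalisation, asymmetric least
  squares baseline removal (asymmetry 0.001, penalty 10⁴, 10 iterations),
  transient detection with frequency/amplitude/FWHM statistics,
  linear-assignment linking of firing events into intercellular tracks
  (90 µm cutoff, 2-frame gap closing), quadrant angle classes, and
  s1–s4 sector histograms with log-normal fits.

* **Synthetic data with ground truth.** Seeded generators for spike trains
  (5 mHz, 15 s FWHM transients), spatially graded propagating event fields
  on the MZ annulus, and rendered image stacks — so every analysis stage is
  testable end-to-end without any imaging data.

## Worked example

```r
library(mzring)

params <- reference_params()                    # calibrated defaults
cut    <- scenario_config("anterior_half")      # oblique cut, offset +2
run    <- simulate_ring(cut, params)
print(run)
```

```
Marginal-zone ring simulation (anterior_half scenario)
  cells: 100 | mode: heaviside | dt: 5e-05 h
  phases: pre-cut 3 h ; post-cut 6 h
  committed cells: 3 | clamped negatives: 0
  streak arcs:
 start_id end_id span onset_h
        8      8    1  2.0322
```

Reading this: during the intact phase the ring committed a 2-cell streak
arc straddling the posterior pole (cells 99 and 0, at t = −2.80 h, i.e.
0.20 h after the start of the 3 h pre-cut phase). The cut removed that arc
obliquely, leaving cell 8 as the posterior-leaning right edge; after the
cut, calcium activity collapsed, BMP4 fell, cVG1 rose transiently at
*both* wound edges, and at 2.03 h the right edge committed — a single new
streak on the posterior-leaning side, while the rescue wave of calcium
activity kept the left edge uncommitted. The mirrored cut
(`obliquity_offset = -2`) commits the left edge instead, and the Hill
variant (`reference_params(production_mode = "hill")`) behaves the same.

On the measurement side:

```r
cfg <- trace_synth_config(seed = 1, n_cells = 150, noise_sd = 8,
                          spike_amplitude_mean = 50, spike_amplitude_sd = 5,
                          spike_amplitude_min = 40)
g   <- make_traces(cfg)                          # traces + ground truth
tr  <- subtract_baseline(                        # ALS baseline removal
         structure(list(times = g$times, values = g$values[, 1]),
                   class = "mz_trace"))
detect_spikes(tr)                                # spike calls for cell 1
trace_stats(detect_spikes(tr), cfg$duration_s)   # frequency in mHz, etc.
```

Across 150 such traces `analysis/02_calcium_traces.R` scores the detector
against the generator and prints:

```
recall 0.984, precision 0.969 (matching window +-15 s)
pooled frequency 5.00 mHz (generating rate 5 mHz)
mean detected amplitude 49.7, mean FWHM 14.4 s
```

— recall and precision above 0.95 in the stated validity regime
(amplitude/noise ≥ 5, inter-spike interval ≥ 2 FWHM), pooled frequency on
the generating 5 mHz, and FWHM within one frame of the generating 15 s.

The `analysis/` scripts run the three full analyses and write their tables
under `results/`:

```sh
Rscript analysis/01_ring_model.R        # both scenarios, both switch variants
Rscript analysis/02_calcium_traces.R    # trace generation -> detection -> scoring
Rscript analysis/03_tracks_and_sectors.R # event field -> tracks, sectors
```

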