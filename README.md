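# ecquant

Quantification of stimulus responses in human enterochromaffin (EC)
cells — the serotonin-producing enteroendocrine cells of the gut
epithelium. Experiments on these cells typically combine four read-outs,
and `ecquant` implements the full quantification chain for each:

1. **Ratiometric imaging** (Fura2 340/380 for Ca²⁺, CFP/YFP FRET for
   cAMP): per-cell perfusion time series are gated by a positive-control
   criterion, and stimulus responses are called by a z-score rule.
2. **Membrane-capacitance electrophysiology**: depolarization-train
   recordings are decomposed into the immediately releasable pool (IRP),
   the readily releasable pool (RRP) and total vesicular release, with a
   quality-control taxonomy for recording inclusion.
3. **Current-clamp action potentials**: spike counts per current step and
   waveform metrics (threshold, overshoot, half-width).
4. **Secretion plates** (5-HT ELISA): per-plate basal normalization and
   fold-change statistics.

Every analysis stage is paired with a seeded synthetic-data generator
that emulates the corresponding acquisition protocol with known ground
truth, so each estimator is testable end to end without access to raw
recordings.

## The core quantification rules

**Responder classification.** For a ratio trace *F*, baseline statistics
are taken over the 60 s of datapoints immediately preceding a test
addition, and every stimulus-epoch sample is scored as

> *z*ₜ = (*F*ₜ − mean *F*\_b) / SD *F*\_b

with the *n*−1 SD. A cell *responds* to a stimulus if *z*ₜ > 3 for at
least 2 consecutive acquired timepoints, and a cell enters the analysis
only if its positive control (KCl or forskolin/IBMX) elevated the ratio
by ≥ 10 %. Per-cell effect sizes are fold changes R/R₀, where R
aggregates (max by default) the ratio over the stimulus epoch and R₀
over the preceding basal window.

**Pool decomposition.** Capacitance trains of 6 × 10 ms then 4 × 100 ms
depolarizations (−70 → +20 mV, 300-ms interpulse measurements) are
summarized by window averages: the Cm gained between the 300-ms window
before pulse 1 and the window after pulse 6 is the IRP; after pulse 10,
the RRP (incremental or cumulative convention, recorded in every
output); and at 7 s after first-pulse onset, total release. All values
are also normalized to initial capacitance (fF/pF). Recordings are
classified as *provoked*, *no exocytosis*, *spontaneous* or *unstable*
from the pulse-locking of Cm increments and per-pulse peak currents.

## Worked example

```r
library(ecquant)

# --- imaging: 48-cell cohort, half carrying a 1.25x response ----------
cfg <- imaging_sim_config(
  n_cells = 48,
  epochs = data.frame(label = "isovalerate", duration = 60, amplitude = 1.25),
  noise_sd = 0.05, responder_fraction = 0.5, seed = 42)
sim <- simulate_imaging_cohort(cfg)
calls <- analyze_imaging(sim$traces, sim$schedule)
summary(calls)
#> Imaging cohort: 48 cells, 48 passed the positive-control gate
#>     stimulus n_included n_responders responder_rate median_fold
#>  isovalerate         48           19      0.3958333    1.047546

r <- one_sample_wilcoxon_vs_1(calls$fold_change[calls$included])
#> median R/R0 1.048 (95% CI 1.010-1.210), Wilcoxon vs 1: p = 8.3e-06

# --- capacitance: one EC-scale cell -----------------------------------
pcfg <- pool_sim_config(irp_size = 3.5, rrp_size = 91,
                        release_fraction_short = 0.6,
                        release_fraction_long = 0.75,
                        noise_sd = 5, cm0 = 10.8, seed = 7)
cap <- simulate_capacitance(pcfg)
pool_decomposition(landmark_deltas(cap$recording), cm0 = 10.8,
                   cell_id = "cell0001",
                   qc_class = qc_classify(cap$recording))
#> Pool estimate for cell0001 (cm0 = 10.8 pF, RRP convention: incremental, QC: provoked)
#>   IRP      2.30 fF  ( 0.213 fF/pF)
#>   RRP     89.74 fF  ( 8.310 fF/pF)
#>   total   90.72 fF  ( 8.400 fF/pF)

# --- action potentials -------------------------------------------------
vt <- simulate_voltage_trace(c(100, 300, 500, 700, 900), 1100,
                             threshold = -23.5, peak = 35.5,
                             half_width = 19.1, rise_slope = 12,
                             sample_interval_ms = 0.1)
detect_spikes(vt)
#> cell0001, step 1 (30 pA): 5 spike(s); resting -70.0 mV
#>   threshold -23.5 mV, overshoot 35.4 mV, half-width 19.1 ms (means)
```

The imaging summary reads: of 48 cells passing the positive-control
gate, 19 were called responders (the cohort carried a true responder
fraction of 0.5 at a modest 1.25× amplitude over 5 % noise — some true
responders fall below the 2-consecutive-z>3 rule at this signal-to-noise),
and the cohort-level fold change is small but highly significant against
a baseline of 1. The pool estimate recovers the configured 3.5 fF IRP /
91 fF RRP construction up to recording noise (IRP released by six short
pulses at a 0.6 per-pulse fraction is 3.5 × (1 − 0.4⁶) ≈ 3.49 fF; the
measured 2.30 fF reflects the 5 fF per-sample noise in the 300-ms
averaging windows), and the spike analysis returns the constructed
waveform exactly.

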