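---
title: "Methods: quantifying enterochromaffin-cell stimulus responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enterochromaffin-cell stimulus responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecquant)
```

`ecquant` packages the quantification chain used to characterize
stimulus responses of human enterochromaffin (EC) cells across four
modalities: ratiometric imaging, capacitance electrophysiology,
current-clamp spiking, and plate-based secretion. This vignette is the
package's own account of the models and conventions behind each stage:
what is computed, under which assumptions, which parameters matter, and
where the design was genuinely open.

## 1. Ratio traces and epochs

Imaging inputs are two-channel fluorescence series per cell. The ratio
is formed after per-sample background subtraction,
$r_t = (A_t - bgA_t)/(B_t - bgB_t)$, where channel A is 340-nm
excitation (Fura2) or CFP emission (FRET cAMP sensor) and channel B is
380 nm or YFP. A non-positive denominator at any sample rejects the
trace with the sample index named — backgrounds that swallow the signal
indicate a segmentation or acquisition fault, not data to be patched.

Perfusion structure is carried by an epoch schedule of labeled,
non-overlapping, **half-open** intervals `[start, end)`. Half-open
semantics make epoch assignment unambiguous on the regular acquisition
grid: adjacent epochs partition the samples with no sample counted
twice. Imaging time is in seconds, electrophysiology in milliseconds —
each instrument's native unit, converted nowhere inside the analyses.

There is deliberately **no resampling or interpolation** anywhere in the
package. The responder rule below counts *consecutive acquired samples*;
any regridding would change its null statistics.

## 2. The z-score responder classifier

For each test epoch, baseline statistics are computed over the 60 s of
datapoints immediately preceding that addition (per-stimulus
re-baselining, so multi-stimulus protocols are scored against their own
local baseline), and every in-epoch sample is scored

$$z_t = \frac{F_t - \overline{F_b}}{\mathrm{SD}(F_b)},$$

with the sample (n−1) SD. A cell responds if $z_t > 3$ — strictly; ties
at exactly 3 are non-responses — for at least 2 consecutive timepoints.
Cells enter the analysis only if their positive control (KCl for Ca²⁺,
forskolin/IBMX for cAMP) elevated the ratio by at least 10 % over the
baseline reference; the boundary is inclusive ("at least"). Gated-out
cells remain in outputs with `included = FALSE` and a reason code so
exclusions are auditable; they are omitted from cohort statistics.

Two properties of this rule are worth calibrating rather than assuming:

* Because the baseline mean and SD are *estimated* from ~30 samples, the
  null distribution of $z_t$ is heavier-tailed than N(0,1) (t-like
  inflation), and consecutive $z$ values are positively correlated
  through the shared baseline estimate. The independence approximation
  $(n_{epoch}-1)\,P(z>3)^2$ therefore **understates** the null responder
  rate severalfold; the test suite calibrates the implemented rule
  against a brute-force Monte Carlo oracle (10,000 package-simulated
  cells against a 100,000-replicate direct simulation) instead of any
  closed form.
* The default fold-change aggregator is the epoch **maximum** (with the
  mean available, and the choice recorded in every output row, because
  figure-legend conventions for Fura2 are ambiguous). The max statistic
  adds the same extreme-value offset to both R and R₀, so the median
  R/R₀ sits slightly *below* the true multiplicative amplitude — a small
  bias the tests quantify against a Monte Carlo oracle rather than
  correct, since it matches how such figures are conventionally
  computed.

## 3. The imaging simulator

`simulate_imaging_cohort()` emulates perfusion imaging at one ratio
sample every 2 s: a 60-s baseline, test epochs in order, and a final
positive-control epoch applied to every cell. Responses are
multiplicative **steps** on the baseline ratio (an optional one-sample
onset ramp is available): the simplest shape that exercises the
consecutive-timepoint rule, chosen over plateau/decay kinetics because
the classifier is insensitive to within-epoch shape beyond run length.
Noise is additive Gaussian **on the ratio**, not on the raw channels —
the analyses operate on ratios, and channel-level noise would add
non-identifiable parameters. Slow drift is linear. Each cell carries the
epoch effect independently with probability `responder_fraction`, and
the ground-truth table records every draw.

What the generator does *not* emulate: photobleaching curvature,
perfusion transients, correlated noise across cells, and cell-to-cell
amplitude heterogeneity. Passing closed-loop tests therefore shows the
estimators are correct for step-plus-noise responses at the acquisition
cadence, not that the rule is optimal for arbitrary response kinetics.

Seeds are mandatory fields of every simulator configuration; there is no
global random state to inherit accidentally.

## 4. Capacitance: depletion model, landmarks, QC

**Forward model.** The pool simulator is phenomenological: short (10-ms)
pulses release a fixed fraction of the *remaining* IRP; long (100-ms)
pulses release a fixed fraction of the remaining RRP, with any remaining
IRP dumped on the first long pulse; a sustained component adds linear Cm
growth during the post-train window; endocytosis (default 0) removes
membrane linearly after the first pulse. Cumulative release after $k$
short pulses is the geometric-depletion sum
$\mathrm{IRP}\,(1-(1-f_s)^k)$, and analogously for long pulses — the
closed form the tests use as an oracle. Cm is emitted **only in
measurement windows** (pre-train, 300-ms interpulse, post-train): the
sine-wave capacitance measurement is physically suspended during
depolarizations, so in-pulse Cm is missing data, never interpolated.

**Landmarks.** All quantification is window arithmetic: the reference is
the mean Cm over the 300 ms before pulse 1, and each landmark is the
mean over the 300 ms after the designated pulse (after pulse 6 for the
IRP, pulse 10 for the RRP, and over the 300-ms window ending 7 s after
first-pulse onset for total release), minus the reference. Windows clip
to available interpulse samples and never cross a pulse. The 7-s
total-release window end is configurable (`total_window_s`) because the
time origin of a "0 to 7 s" convention is protocol metadata, not
physics; this package anchors it at first-pulse onset.

The RRP is reported under an explicit convention: `incremental`
(default; Cm beyond the IRP) or `cumulative` (IRP included). The IRP is
small relative to the RRP so both conventions give similar magnitudes,
but the choice is recorded in every output to prevent silent
disagreement between analyses.

**QC taxonomy.** Recording inclusion follows four operational classes:

* `no_exocytosis`: total ΔCm within $k$ baseline-window SDs of zero
  (default $k = 3$) *and* overall Cm variability within the same floor,
  despite robust inward currents (|peak| above a threshold, default
  20 pA, on at least half the pulses);
* `provoked`: total ΔCm above the floor and Cm increments locked to the
  pulses;
* `spontaneous`: Cm wanders above the floor without pulse locking;
* `unstable`: caller-set flag for access-resistance/conductance
  problems (those diagnostics live upstream of this package).

Pulse locking is measured as the rank-biserial correlation
($2\,\mathrm{AUC}-1$) between Cm increments across pulses and increments
across equal-length pulse-free gaps tiled into the post-train window.
A rank statistic is used because depletion-type responses are extremely
skewed — one long pulse can carry most of the released Cm — which breaks
a Pearson correlation against a pulse indicator. The default lock
threshold of 0.4 is about two null SDs of the statistic for the
10-pulse train ($\mathrm{SD} \approx 0.21$ for 10 pulse vs 30 control
windows under no locking). One known limitation: a strong sustained
(post-train) release component raises the control increments and
suppresses the lock statistic, so heavily sustained cells can read
`spontaneous`; classify QC on recordings where the post-train window is
dominated by measurement noise, or lower the lock threshold for such
protocols.

**Potentiation protocol.** The 15 × 500-ms train (−60 → 0 mV) is
quantified as a single landmark: mean Cm over 300 ms after the last
pulse minus the pre-train reference, in fF and fF/pF.

## 5. Action potentials

Spikes are counted as upward crossings of a fixed **detection level**
(default −20 mV) within the annotated current step, with a refractory
lockout (default 5 ms). The detection level is deliberately distinct
from the biophysical **AP threshold**, which is estimated per spike as
the membrane potential at the start of the last dV/dt run exceeding a
slope criterion (default 10 mV/ms) before the peak — taking the *last*
super-criterion run keeps earlier spikes' upstrokes from bleeding into
the estimate, and tolerates the slope blending that sampling introduces
at the peak. Overshoot is the spike peak; half-width is the duration at
the level midway between threshold and peak, located by linear
interpolation for sub-sample resolution.

The voltage simulator builds piecewise-linear spikes: a slow
sub-criterion foot from baseline to threshold, a fast upstroke, and a
repolarization timed so the half-amplitude width equals the configured
value. This makes all three waveform metrics exactly recoverable (up to
sampling), which is what the closed-loop tests assert. Real EC-cell
spikes are smooth and broad; the simulator's geometry is a test harness
for the estimators, not a biophysical model — a conductance-based model
is out of scope by design.

## 6. Secretion plates

Wells are normalized to the mean of the **basal wells on the same
plate**, which makes the basal folds average exactly 1 per plate and
removes plate-level scale (folds are invariant to rescaling a plate).
Wells outside the ELISA quantification range (defaults 0.015–2.5 ng/mL)
are clipped to the bound and flagged; flagged wells are excluded from
basal means and condition tests by default and includable by argument —
the kit range is a measurement-validity bound, not a statistical
preference. Condition-level inference is a two-sided one-sample t-test
of the fold changes against 1, with zero-variance inputs returning a
flagged non-result rather than an exception. Wells are the default
experimental unit; replicate averaging per batch is the caller's
decision upstream.

The plate simulator draws well concentrations log-normally with a
configured mean and fractional CV (`cv = 0` degenerates to exact
values); its defaults emulate the assay being modeled — basal mean
0.47 ng/mL within a 0.015–2.5 ng/mL range.

## 7. Cohort statistics

Cohort fold-change significance uses the one-sample Wilcoxon signed-rank
test against 1 (imaging folds are not normally distributed), with values
tied at exactly 1 dropped per the signed-rank convention and counted in
the output, and a median CI from order statistics (sign construction,
conservative coverage). Repeated-measures designs use the Friedman test
with Dunn's post-hoc z-tests on mean within-block ranks (tie-corrected);
the pairwise family defaults to control-versus-treatment, mirroring how
such comparisons are typically structured, with Bonferroni adjustment.
Two-group and multi-group designs dispatch to Mann-Whitney, paired t, or
one-way ANOVA with Dunnett contrasts (via `multcomp`). Degenerate inputs
(fully tied Friedman blocks, zero-variance paired differences) return
flagged limit results. Dunn's rank post-hoc is implemented in-package;
the standard tests are the `stats` implementations.

`cohort_report()` writes the tidy tables plus a JSON manifest (config,
config fingerprint, seed, package version) and a run log. Outputs are
deliberately timestamp-free and path-relative so a re-run with identical
inputs is byte-identical — determinism is a contract, tested end to end.

## 8. Problem sizes and numerical tolerances

The test suite and `scripts/acceptance.R` use: 10,000 simulated null
cells (30 baseline + 30 epoch samples each) against a
100,000-replicate oracle for null calibration; 500 cells per amplitude
on the grid {1.0, 1.05, 1.1, 1.2, 1.5} at 5 % noise for sensitivity;
100 seeded capacitance cells at 5 fF noise for landmark recovery, with
the acceptance bound $2\sigma/\sqrt{30}$ reflecting the 30 Cm samples
per 300-ms window; and 1,000 simulated plates against a
2,000-replicate oracle for secretion test power. Window arithmetic on
noiseless fixtures is exact to <1e-9 fF; depletion-model closed-loop
checks use a 0.1 fF tolerance (grid quantization of window centers);
spike half-width is recovered within one sample interval.

## 9. Known limitations

* The simulators are phenomenological throughout; no conductance-based
  EC-cell model, no image segmentation, no instrument file formats.
* The responder rule's operating characteristics are calibrated for the
  2-s acquisition cadence; at other cadences the 60-s baseline holds a
  different sample count and the null rate shifts accordingly.
* The QC lock statistic assumes the post-train window is
  noise-dominated (see §4).
* Out-of-range secretion wells are clipped-and-flagged, not imputed;
  heavy censoring will bias plate means toward the range bounds.
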