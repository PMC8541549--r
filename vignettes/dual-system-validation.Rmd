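---
title: "Validating a dry-electrode EEG system against gel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a dry-electrode EEG system against gel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dry multipin EEG electrodes trade preparation time for higher electrode-skin
impedance, which shows up mainly as excess low-frequency noise and a larger
fraction of unusable data. Deciding whether a dry cap is "good enough"
requires a paired comparison against a conventional gel cap on the same
subjects, across the three domains in which EEG is consumed: time
(evoked potentials), frequency (spectral power), and space (scalp
topographies). `eegcompare` implements that comparison as a reusable,
fully testable pipeline, together with a paired-session simulator so that
every stage can be validated against known ground truth without access to
laboratory recordings.

# The data model and study design emulated by the simulator

The simulator generates, per subject, one dry and one gel session of three
tasks at 1024 Hz:

* **Checkerboard (CHECK)** — 300 pattern reversals every 0.45 s evoking a
  visual evoked potential (VEP) with occipital N75/P100 components.
* **Auditory steady-state response (ASSR)** — 75 trials of 12 s
  amplitude-modulated tones (40 Hz modulation of a 500 Hz carrier) with a
  jittered 2–3 s intertrial interval; an auditory N1/P1 complex occupies
  the first second of each trial and a 40 Hz steady-state component runs
  throughout, both fronto-central.
* **Eyes open / eyes closed (EOEC)** — 30 alternations of 5 s open /
  3 s closed; occipito-parietal alpha (8–13 Hz) power is multiplied by
  `alpha_ec_gain` while the eyes are closed (the Berger effect).

Evoked components are separable products of a fixed Gaussian scalp field
(centered on Oz for the VEP, between Fz and Cz for the auditory responses,
behind Pz for alpha) and a Gaussian time course at the component latency.
Component amplitudes are expressed at the field center; the defaults were
calibrated once from the spatial standard deviation of those fields so that
epoch-averaged global field power peaks land in the 8–13 µV range typical
of these paradigms. Latencies default to 0.121/0.152 s (VEP) and
0.313/0.410 s (AEP), i.e. the nominal component latencies plus the constant
stimulus-presentation delay such setups exhibit; the peak search windows
default to matching ranges and are configurable.

The noise model is: pink (1/f) background per channel, independent white
sensor noise, a drift with a random-walk (1/f²) spectrum band-limited
below 1 Hz and stronger for the dry cap, a reference-electrode noise trace common to all recorded
channels (the dry cap is natively M2-referenced; the gel cap records
against CPz, whose trace cancels exactly when the data are re-referenced
to the recorded M2 channel — re-referencing therefore adds the M2
electrode's intrinsic noise, for both systems alike), coherent 50 Hz line
noise, and Poisson-process blinks —
a stereotyped ~400 ms biphasic waveform whose amplitude decays with
distance from the frontal midline. Two asymmetries distinguish the dry
system: `effect_scale_dry_delta` multiplies its sub-4 Hz power (default 2,
matching the roughly twofold delta-power excess such systems show), and a
higher per-channel corruption probability (default 0.10 vs 0.035) injects
flat, high-amplitude, or drifting channels. Subject-level latent amplitude
scales are drawn once per subject and shared between that subject's two
sessions, which is what makes between-system correlations high by
construction. Each (subject, system, task) triple draws from its own
deterministic stream derived from the master seed, so partial re-runs are
reproducible bit for bit.

What the simulator does **not** emulate: volume-conducted spatial
correlation of the background noise (channels are independent up to the
deterministic sources), biophysical forward models, electrode-skin
impedance dynamics, movement artifacts, and non-stationary alpha. Passing
tests therefore demonstrate that the *analysis* is correct and calibrated,
not that it has been validated against the full complexity of real
recordings.

# Preprocessing and the rejection cascade

Recordings pass through a zero-phase 2nd-order Butterworth 1–48 Hz
bandpass followed by a 48–52 Hz bandstop (applied in that order;
forward–backward filtering squares the magnitude response and cancels the
phase). Channels with a task-wide mean absolute amplitude below 1 µV
(flat) or above 50 µV are dropped. "Average amplitude" is read as mean
absolute value: the signed mean of high-passed data is ≈ 0 and would
reject everything under the 1 µV rule.

Blink removal operates on any linear decomposition that reconstructs the
data (`mixing %*% sources`); the package's default splits off the spatial
common mode (reference-electrode noise) as its own component and
decomposes the differential remainder by SVD/PCA; an externally computed
ICA can be supplied instead. The
blink component is selected by three criteria: frontal concentration of
the mixing vector (energy fraction on Fp1/Fp2/F7/F3/F4/F8 ≥ 0.6),
a minimum count of stereotyped large monophasic source deflections, and
task-independence (coefficient of variation of deflection counts across
session thirds ≤ 0.5). At most one component is removed — the criteria
describe one ocular source, and removing more risks deleting brain signal.

The gel session is re-referenced to the right mastoid (M2) by subtracting
its recorded M2 channel — the dry cap's native reference — after which
both systems are reduced to their 29 shared channels. Per task (extracted
with 5 s of padding), channels are rejected when (1) the amplitude bounds
above fail, (2) the task-mean absolute amplitude exceeds mean + 2 SD over
channels, or (3) Hann-windowed band power exceeds mean + 2 SD over
channels in ≥ 2 of the 5 canonical bands (window lengths: VEP 0.5 s,
AEP 0.8 s, ASSR 11 s, EOEC 3 s). Trials and 1 s windows are then flagged
per channel against that channel's own mean + 2 SD across units, with
task-specific band subsets (VEP/AEP: delta–beta, ≥ 2 bands; ASSR windows:
gamma only; EOEC windows: all five, ≥ 2 bands).

All mean + 2 SD thresholds are computed in a single pass, include the
candidate in the statistics, use the sample SD, and reject on strict
inequality — so a set of identical channels is never rejected. A known
limitation of this (deliberately simple) design is masking: two similar
gross outliers inflate the mean + 2 SD threshold and can shield each
other. The monotonicity property test therefore exercises the case that
is guaranteed by construction (adding a flat channel never un-rejects an
existing outlier); iterative re-computation would remove the masking but
is not part of the validated design.

Rejected data are accounted in channel-seconds: a rejected channel
contributes its task duration, a rejected unit its window length, and the
subject-level percentage is rejected channel-seconds over total
channel-seconds.

# Time, frequency and spatial analyses

**Global field power.** GFPt is the spatial standard deviation of the
instantaneous potential across channels (population variance), equal to
the pairwise form `sqrt(sum_ij (U_i - U_j)^2 / (2 n^2))`; the tests
verify the identity against a brute-force double sum. Per subject, dry
and gel GFPt series are compared by Spearman rank correlation and RMSD;
cohort summaries report median ± SD. Component peaks are the GFPt maxima
inside the configured windows (ties to the earliest sample).

**Spectra.** PSDs are Welch estimates: Hann-tapered, overlap-averaged
periodograms with one-sided density scaling (µV²/Hz), equal weights
across surviving windows and trials. The ASSR analysis removes seven
temporo-occipital channels with weak 40 Hz responses (T7, T8, P7, P8, O1,
O2, Oz), filters 30–48 Hz, drops each trial's first second (the AEP), and
uses 4 s windows with 75 % overlap. A 4 s window has a native 0.25 Hz
grid; the 40 Hz metrics are read on the 0.5 Hz-spaced 21-bin analysis
strip over 35–45 Hz, whose 20 non-signal bins form the noise set. The SNR
is the 40 Hz power divided by the sample SD over those noise bins, and is
invariant to global spectral rescaling. Z-standardization is per channel
across the frequency bins of the analysis range (35–45 Hz for ASSR,
1–48 Hz for EOEC) — the only axis that yields unitless per-channel
spectra — and subject-level standardized metrics average the per-channel
Z values. EOEC band power uses 1 s windows with 50 % overlap on the
middle 3 s of eyes-open trials and the full 3 s of eyes-closed trials;
band power is the mean over bins whose center lies in [low, high) (the
last band closed). Because 1 s QC windows and longer taper windows tile
the data differently, a taper window enters the PSD only when every
1 s QC window it covers is clean for that channel.

**Topographies and statistics.** Per-electrode values are interpolated
with a biharmonic (thin-membrane) spline — Green's function
`r^2 (ln r - 1)` plus an affine part under the usual moment constraints,
so the map passes exactly through the electrodes and reproduces constant
and linear fields exactly. The grid is 66 × 66 cells tiling [−1, 1]²
masked to cell centers inside the unit head disc (3436 pixels; a
`grid_resolution` key scales this down for fast runs). Missing electrodes
drop out of the interpolation; no imputation. Standardized maps are
Z-scored across masked pixels.

Between-system map differences are tested with a paired sign-flip
permutation test: in a paired design, permuting a subject's condition
labels equals negating its difference map, so all 2ⁿ sign patterns form
the exact null (full enumeration for n ≤ 20 — 32,768 patterns at n = 15 —
Monte-Carlo with the identity pattern included otherwise). Each
iteration's paired t-map is converted pixelwise to a Z-map using the
per-pixel permutation mean and SD; recording each iteration's map-wide
minimum and maximum and taking their 2.5th/97.5th percentiles gives
thresholds that control the family-wise error at 5 % (the max-statistic
construction). Keeping thresholds and observed values on one common Z
scale is the coherent reading of a procedure that derives thresholds from
t extremes but tests Z values. The per-pixel permutation mean is exactly
zero under full enumeration (sign symmetry), which the implementation
exploits by enumerating half the patterns and mirroring the extremes.

Scalar metrics are compared with two-sided Wilcoxon signed-rank tests;
the five EOEC bands use a Bonferroni-adjusted level of 0.05/5 = 0.01.
Between-system agreement of per-electrode metrics is a pooled Spearman
correlation over all (subject, electrode) pairs with average ranks on
ties and pairwise removal of missing entries.

# Numerical choices and degenerate inputs

* Sample indices are 0-based; epochs are half-open sample intervals of
  length `round((tmax - tmin) * fs)`; baseline correction subtracts the
  per-trial, per-channel mean over [−0.1, 0) s.
* VEP epochs (0.5 s) overlap successive reversals (0.45 s apart); the
  overlap is part of the paradigm and is permitted.
* A constant GFP series leaves Spearman's rho undefined; it is reported
  as `NA` with a warning rather than silently coerced.
* Zero noise-bin SD makes the SNR undefined (`NA` with a diagnostic);
  a flat spectrum makes Z-standardization an error.
* A numerically singular interpolation system falls back to a small
  ridge with a warning; duplicate electrode positions are an error.
* All-zero difference maps yield no significant pixels and a warning.
* Quantile type 7 (R's default) defines the permutation thresholds.
* EDF output is 16-bit with per-channel physical scaling, so a round
  trip is exact to within half a quantization step of each channel's
  range; the delimited text format is lossless.

# Problem sizes used in the shipped checks

The package's own validation runs use scaled-down problem sizes chosen to
keep the full suite fast while leaving every condition parameter at its
default: test cohorts use 128–256 Hz sampling, tens rather than hundreds
of trials, and reduced (16–24 point) topography grids; the family-wise
error calibration uses 200 replicate 15-subject null cohorts on a 20 × 20
grid with full 2¹⁵ enumeration, and the effect-recovery check uses 100
replicate cohorts with the eyes-closed alpha gain at 4 and the dry delta
excess at its default of 2. The acceptance script runs the complete
pipeline on a 15-subject cohort at 256 Hz with 60 reversals, 6 ASSR
trials and 6 EOEC cycles on a 24-point grid.

# Known limitations

* The simulator's channel-independent background understates spatial
  correlation, which makes interpolated null maps rougher than real ones;
  the permutation test's calibration does not depend on this, but
  absolute significant-pixel percentages on simulated effects should not
  be read as predictions for real data.
* The single-pass mean + 2 SD cascade can mask pairs of similar gross
  outliers (see above).
* The default PCA decomposition separates blinks well because the
  simulated blink is large and spatially stereotyped; on real data an
  ICA is the better decomposition, and the selection criteria accept one
  unchanged.
* The analysis assumes both sessions share the 29-channel montage after
  harmonization; caps with different layouts would need montage tables
  extended beyond the built-in 10-10 set.
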