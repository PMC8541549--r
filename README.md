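# eegcompare

Paired validation of a dry-electrode EEG system against a conventional
gel-electrode system, implemented as a complete, testable R pipeline:
preprocessing, a multi-criteria rejection cascade, time-domain
(ERP / global field power), frequency-domain (Welch PSD, 40 Hz
steady-state response, band power), and spatial-domain (biharmonic scalp
topographies with permutation testing) comparisons — plus a
paired-session simulator so the whole analysis runs end to end with no
external data.

## Who this is for

Groups evaluating novel EEG hardware (dry, textile, in-ear electrodes)
against a reference system on the same subjects, and anyone who needs a
calibrated implementation of the underlying statistical machinery:
mean + 2 SD artifact-rejection cascades, GFP-based ERP comparison, ASSR
SNR estimation, and sign-flip permutation tests with pixel-based
family-wise error correction.

## The statistics at the core

**Global field power.** At each time point, with channel potentials
$U_1,\dots,U_n$,

$$\mathrm{GFP}_t \;=\; \sqrt{\tfrac{1}{2n^2}\sum_{i=1}^n\sum_{j=1}^n (U_i-U_j)^2}
\;=\; \mathrm{SD}_{\text{spatial}}(U),$$

the spatial standard deviation of the instantaneous scalp map. Dry and
gel GFP time courses are compared per subject by Spearman correlation
(COR) and root mean square deviation (RMSD, µV); component peaks (N75,
P100, N1, P1) are GFP maxima in configurable windows.

**40 Hz ASSR SNR.** With $P(f)$ the Welch PSD (4 s Hann windows, 75 %
overlap) on the 0.5 Hz-spaced 35–45 Hz analysis strip,

$$\mathrm{SNR} \;=\; \frac{P(40\,\mathrm{Hz})}{\mathrm{SD}\bigl(P(f),\; f \in \text{noise bins}\bigr)},$$

with the 20 non-signal bins of the strip as the noise set. Both absolute
(µV²/Hz) and per-channel Z-standardized spectra are supported.

**Pixel-corrected permutation test.** Per-subject condition maps are
interpolated with a biharmonic spline onto a disc-masked pixel grid. In a
paired design, permuting a subject's condition labels equals negating its
difference map, so all $2^n$ sign patterns form the exact null
(enumerated fully for $n \le 20$). Per pattern the paired t-map
$t = \bar X_D / (S_D/\sqrt n)$ is converted pixelwise to
$Z = (t - \bar H_0)/S_{H_0}$, and the 2.5th / 97.5th percentiles of the
map-wide minima / maxima give thresholds that control the family-wise
error at 5 %.

Scalar metrics use two-sided Wilcoxon signed-rank tests (Bonferroni
0.05/5 = 0.01 across the five EOEC bands) and pooled electrode-pair
Spearman correlations. Rejected data are accounted in channel-seconds.

## A worked example

```r
library(eegcompare)

cfg <- pipeline_config(
  sim = sim_config(n_subjects = 3, sample_rate = 256,
                   check_n_reversals = 20, assr_n_trials = 3,
                   eoec_n_cycles = 4, seed = 5),
  grid_resolution = 16)
bundle <- run_pipeline(cfg)
generate_report(bundle)
```

prints (abridged):

```
Dual-system EEG comparison: 3 subjects
VEP GFP comparison: rho median 0.855 (SD 0.082), RMSD median 0.272 uV (SD 0.099)
  dry N75: amplitude 6.07 +- 0.51 uV, latency 0.117 +- 0.000 s
  dry P100: amplitude 9.13 +- 0.73 uV, latency 0.152 +- 0.000 s
ASSR 40 Hz power (abs): dry 0.328, gel 0.335 uV^2/Hz; SNR (abs): dry 4.42, gel 2.97
EOEC EC electrode-pair Spearman: delta -0.23, theta -0.27, alpha 0.83, ...
Topography P100: 0.0% of pixels significant
Rejected data: dry 5.9%, gel 4.3% (subject means)
```

Reading it: the two systems' VEP global field power agrees strongly in
rank (rho 0.86 on this tiny cohort) with sub-microvolt RMSD; the
recovered P100 latency (0.152 s) matches the injected component; the
40 Hz steady-state response stands 3–4 SDs above its spectral noise
floor; alpha band power — the one band carried by a spatially coherent
source — correlates strongly across electrodes between systems; no
topography pixel differs significantly between systems (none should —
the simulated evoked content is identical by construction); and the dry
session loses more data to the rejection cascade than the gel session,
driven by its higher channel-corruption rate and drift.

Individual stages are plain functions: `simulate_cohort()`,
`filter_zero_phase()`, `flag_bad_channels_task()`, `extract_epochs()`,
`gfp_timecourse()`, `welch_psd()`, `assr_metrics()`, `make_topomap()`,
`permutation_pixel_test()`, … — see the vignette in `vignettes/` for the
methods and design rationale.

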