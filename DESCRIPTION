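Package: eegcompare
Title: Paired Validation of Dry and Gel EEG Electrode Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating a dry-electrode EEG system against a
    conventional gel-electrode system recorded from the same subjects.
    Implements the full comparison pipeline: zero-phase Butterworth
    filtering, channel harmonization and mastoid re-referencing, a
    mean + 2 SD multi-criteria rejection cascade (channels, trials,
    windows), event-related potential averaging with global field power
    (GFP) comparison by Spearman correlation and RMSD, Welch power
    spectral density with Z-standardization, 40 Hz auditory steady-state
    response power and SNR, eyes-open/eyes-closed band power, biharmonic
    spline scalp topographies, and a sign-flip permutation test with
    pixel-based (max-statistic) correction for multiple comparisons.
    A paired-session simulator generates dry/gel cohorts with known
    ground truth so the whole analysis can be exercised end to end
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
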