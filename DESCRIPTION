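Package: assrgating
Title: Auditory Steady-State Response and Inhibitory Gating Analysis of Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies two electrophysiological read-outs from epoched local
    field potential (LFP) recordings: the 40-Hz auditory steady-state response
    (ASSR), via complex Morlet wavelet decomposition summarised as mean trial
    power (MTP) and phase-locking factor (PLF), and paired-pulse inhibitory
    gating (IG), via windowed evoked-potential peak amplitudes, control-period
    significance testing and test/conditioning (T/C) amplitude ratios.
    Includes readers for EDF and CSV continuous recordings with event
    sidecars, epoching and zero-phase band-pass filtering, a synthetic LFP
    generator with region- and anesthesia-specific presets for the auditory
    cortex, hippocampus, amygdala and prefrontal cortex, and group-level
    statistics (one-way ANOVA with Tukey HSD contrasts across regions, paired
    t-tests across conscious versus anesthetized conditions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'EpochSet-methods.R'
    'assrgating-package.R'
    'runconfig.R'
    'io-continuous.R'
    'io-epochs.R'
    'synthetic.R'
    'tfr.R'
    'gating.R'
    'group-stats.R'
    'pipeline.R'
    'utils.R'
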