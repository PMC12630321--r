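Package: petco2lag
Title: End-Tidal CO2 Lag Mapping for BOLD and Diffusion fMRI Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits vascular (CO2-driven) contamination of fMRI contrasts.
    Builds end-tidal CO2 (pETCO2) regressors from raw expired-CO2 traces,
    computes apparent diffusion coefficient (ADC) timeseries from interleaved
    two-b-value diffusion acquisitions, maps voxelwise lagged correlation and
    latency against the regressor, derives phase-randomization surrogate
    significance thresholds, runs a noise-amplification control, and computes
    group summary and reproducibility statistics. Includes a synthetic-data
    generator emulating breath-hold and resting-state physiology so the whole
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
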