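Package: lsoephys
Title: Intracellular Electrophysiology Analysis for Lateral Superior Olive Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo patch-clamp recordings from the
    lateral superior olive (LSO), the brainstem nucleus that encodes
    interaural level differences (ILD). Implements the membrane-potential
    feature set that separates principal from non-principal LSO neurons:
    the upper cutoff frequency of the amplitude spectrum of wavelet-denoised
    spontaneous activity, action-potential amplitude, evoked-response
    temporal profiles (peak-to-sustained ratios), interspike-interval
    regularity ("chopper") analysis, ILD tuning-curve sigmoid fits, input
    resistance from current steps, and anatomical measures (normalized
    lateromedial position, somatic synaptic coverage, tonotopy). A synthetic
    recording generator with ground-truth labels makes every stage testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
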