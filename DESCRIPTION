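Package: microstab
Title: Metabolic Diversity and Wavelet-Variance Stability of Bacterial Microcosms
Version: 0.1.0
Authors@R:
    person("Microstab", "Developers", email = "microstab@example.org", role = c("aut", "cre"))
Description: Tools for biodiversity-ecosystem-function analyses of bacterial
    microcosms. Computes community metabolic diversity (CMD), niche breadth,
    Jaccard niche overlap and functional redundancy from binary Biolog-GN-style
    substrate-affinity profiles; quantifies the temporal stability of redox
    potential (Eh) time series via a continuous Morlet wavelet transform and
    its scale-averaged wavelet variance (stability = 1/Vt); correlates
    stability and decomposition endpoints (ETSA, DOC proxy) with species
    richness and CMD; and generates fully synthetic microcosm experiments with
    known ground truth, including overlap-dependent compensatory abundance
    dynamics, so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
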