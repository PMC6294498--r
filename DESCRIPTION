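Package: cspfit
Title: NMR Chemical Shift Perturbation Titration Analysis with Global
    Dissociation-Constant Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of two-dimensional 1H-15N HSQC ligand titrations of
    proteins: reading Sparky and tabular peak lists, tracking assigned
    amide peaks across titration points, computing weighted 1H/15N
    chemical shift perturbations (CSPs), detecting saturation,
    classifying fast/intermediate/slow chemical exchange, and globally
    fitting a one-site binding isotherm with a shared dissociation
    constant and residue-specific maximal CSPs (standard errors from the
    covariance matrix of the fit).  Also implements dual-luciferase
    reporter (stem-loop assay for polyadenylation) normalization and
    statistics and nuclear/cytoplasmic intensity-ratio summaries, plus
    seeded synthetic-data generators (two-site exchange peak
    trajectories under a one-site equilibrium, triplicate reporter
    wells, per-cell box intensities) so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
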