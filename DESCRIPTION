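Package: blastkin
Title: Blast-Dose Kinetics of Serum Amyloid-Beta Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates serum amyloid-beta 42 (Abeta42) kinetics after blast
    overpressure exposure. A threshold dose model converts weapons-training
    blast histories into mechanical damage and phasic (hyperacute and acute)
    neurobiological response states; these modulate amyloid precursor protein
    synthesis, which feeds an amyloidogenic cleavage cascade and a whole-body
    physiologically based pharmacokinetic (PBPK) transport model spanning
    brain interstitial fluid, brain vasculature, perivascular space, plasma,
    peripheral tissue, and lymph. Includes calibration of the synthesis
    amplification constant against serum draws, a validation layer (relative
    percent errors, exact paired Wilcoxon signed-rank test, over-approximation
    fractions, regression diagnostics), and a seeded synthetic-cohort
    generator emulating a three-day repeated low-level blast training design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
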