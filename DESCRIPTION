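Package: mmrblot
Title: Western Blot Densitometry and Mismatch Repair Protein Ratio Screening
Version: 0.1.0
Authors@R:
    person("Sam", "Okafor", email = "sokafor@example.org", role = c("aut", "cre"))
Description: Simulates and quantifies multiplex western blots of the DNA
    mismatch repair proteins MLH1 (80 kDa) and MSH2 (100 kDa), as used in
    lymphocyte-based carrier screening for Lynch syndrome. Provides a
    synthetic blot and cohort generator with known ground truth (gene-dosage
    carrier effects, PHA stimulation kinetics, film noise), lane and band
    densitometry with equivalent-area background subtraction and a
    detectability rule, the smaller-over-larger MMR ratio statistic with
    replicate reproducibility summaries, and cohort-level bimodality analysis
    via two-component Gaussian mixture fits with BIC model choice and
    posterior mode assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
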