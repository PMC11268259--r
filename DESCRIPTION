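Package: aerosilica
Title: Physicochemical Characterization of Protein-Loaded Mesoporous Silica
    Dry-Powder-Inhaler Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein-loaded mesoporous silica particle
    (MSP) dry-powder-inhaler formulations. Computes BET specific surface area,
    BJH pore-size distributions and total pore volume from nitrogen sorption
    isotherms; quantifies protein loading by supernatant mass balance,
    Langmuir isotherm fits and a pore-filling capacity model; fits the
    correlation-length model (Porod power law plus Lorentzian) to 1-D SAXS
    curves; reduces Next Generation Impactor deposition data to fine particle
    fraction, MMAD and GSD; computes interval and cumulative protein release
    under withdrawal/replacement sampling, silica dissolution percentages and
    T50; segments thermograms into water, protein, salt and carrier mass
    fractions; and fits four-parameter logistic dose-response curves. A
    synthetic-data module generates every input with known ground truth so
    all stages are testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
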