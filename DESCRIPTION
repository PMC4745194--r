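Package: gbmcsc
Title: Tumor-Immune Dynamics of Glioblastoma with Cancer Stem Cells under
    CTL Immunotherapy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a seven-variable ordinary differential equation model
    of glioblastoma multiforme that distinguishes differentiated tumor cells
    from cancer stem cells and couples them to alloreactive cytotoxic
    T lymphocytes, the cytokines TGF-beta and IFN-gamma, and MHC class I/II
    receptor expression. Locates cure, recurrence and coexistence equilibria,
    classifies their stability from Jacobian eigenvalues, certifies
    dissipativity, and computes the treatment-rate thresholds (minimal dose,
    amplification factor, and sufficient cure dose) that separate tumor
    persistence from a globally stable cure state. Includes a numerical
    checker for the structural assumptions the abstract model places on its
    interaction functions, a quasi-steady-state reduction of the fast
    TGF-beta dynamics, and a configuration-file driven command-line surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
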