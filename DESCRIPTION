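Package: synergyci
Title: Median-Effect Dose-Response Modeling and Combination Index Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of drug-combination cytotoxicity data by
    the median-effect method: fits the median-effect dose-response law
    fa/fu = (D/Dm)^m to viability data, computes combination index (CI) and
    dose-reduction index (DRI) for constant-ratio two- and three-drug
    combinations at arbitrary effect levels, and derives reduced-dose
    regimens. Includes plate-reader viability normalization, Annexin-V/PI
    apoptosis quadrant gating, DNA-content cell-cycle fractions, doubling-time
    estimation from growth curves, and synthetic-data generators that emulate
    the statistical structure of plate and flow-cytometry experiments so the
    full pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
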