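Package: cmost
Title: Microsimulation of Colorectal Cancer Natural History and Screening
Version: 1.0.0
Authors@R: person("CMOST", "Maintainers", email = "cmost@example.org",
    role = c("aut", "cre"))
Description: An individual-level, quarterly-step microsimulation of the
    adenoma-carcinoma sequence in the colon and rectum.  Simulates adenoma
    initiation, progression, regression and malignant transformation across
    13 colonic segments, preclinical cancer sojourn, stage-specific survival
    and competing mortality from a period life table.  Supports colonoscopy,
    rectosigmoidoscopy and stool-test screening with complications,
    polypectomy and guideline surveillance; accrues procedure, complication
    and three-phase treatment costs with discounting; and calibrates the
    natural-history parameters against epidemiological benchmarks
    (adenoma prevalence, SEER-style incidence and mortality, stage
    distributions, trial effect sizes) with a greedy search followed by
    Nelder-Mead refinement.  Ships scenario runners for sigmoidoscopy trial
    emulation, decennial colonoscopy and single-colonoscopy age sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
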