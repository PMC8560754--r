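Package: renalmps
Title: Renal Clearance and Whole-Body Pharmacokinetics from Kidney
    Microphysiological System Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Translates perfusion data from a vascularized proximal-tubule
    microphysiological system (organ-on-chip) into human renal clearance and
    whole-body parent-metabolite pharmacokinetics, worked for morphine and
    its active metabolite morphine-6-glucuronide. Provides reduction of
    dual-channel effluent time courses to apparent and intrinsic transport
    clearances and permeability, cell-number-based in vitro-in vivo
    extrapolation of tubular secretion, a dynamic mechanistic kidney model
    with unbound filtration, segmental active secretion and filtrate
    pH-dependent bidirectional passive permeation, a chronic kidney disease
    scaling rule, a perfusion-limited whole-body PBPK model with a
    well-stirred liver and parent-to-metabolite formation, model evaluation
    by absolute average fold error with a twofold acceptance rule,
    non-compartmental analysis utilities, and synthetic-data generators for
    effluent series and clinical-style observations with known ground truth.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
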