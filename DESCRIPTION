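Package: vesiflux
Title: Quantitative Analysis of Proteoliposome Flux Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts radiotracer uptake measured in reconstituted
    proteoliposomes into intraliposomal substrate concentrations using a
    geometric vesicle model (lipids per vesicle, vesicle number, total
    internal volume), computes fold-accumulation statistics, and classifies
    transport phenotypes as channel-like (non-concentrative) or
    concentrative. Includes Michaelis-Menten and turnover-number kinetics,
    four-parameter log-logistic displacement and inhibition fitting
    (EC50/IC50), Nernst diffusion-potential and single-channel conductance
    estimation, and seeded simulators that generate uptake time courses,
    rate tables, dose-response isotherms and current-voltage records with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
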