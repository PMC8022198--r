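Package: pcfba
Title: Proteome-Constrained Flux Balance Analysis for Fermentative Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates proteome-constrained (metabolism-and-expression)
    metabolic models in which every metabolic flux is coupled to the synthesis of
    its catalyst under a fixed total-proteome budget. Provides the two-layer model
    builder (reversible-reaction splitting, isozyme expansion, dummy-protein
    assignment, gene-expression reactions for transcription, translation,
    degradation and dilution), glucose-limited chemostat simulation by binary
    search over the extracellular glucose concentration with Michaelis-Menten
    transporter kinetics, scaled reduced-cost and sensitivity analyses, a twofold
    parameter-robustness scan, and a three-pathway ATP-allocation model that
    explains the switches between mixed-acid fermentation, lactate formation and
    arginine catabolism in lactic acid bacteria. A bundled synthetic fermentative
    network and chemostat dataset generator make every analysis runnable without
    external data. Linear programs are solved with a dense two-phase simplex
    implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
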