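Package: ribospike
Title: Spike-In Standards and Factor-Analysis Normalization for Ribosome
    Profiling
Version: 0.1.0
Authors@R:
    person("ribospike", "maintainers", email = "ribospike@example.org",
           role = c("aut", "cre"))
Description: Design of miRNA-mimicking spike-in oligomer panels for
    ribosome profiling, construction of modified-Latin-square spike-in
    pools with analytically known truth tables, negative-binomial
    simulation of ribo-seq count matrices, control-gene factor-analysis
    normalization anchored on spike-ins, trimmed-mean-of-M-values global
    scaling, moderated-t differential translation tests, and an
    evaluation framework quantifying how global scaling distorts results
    when a genuine global shift in translation exists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
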