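Package: purisel
Title: Purifying Selection and Selection-Corrected Molecular Clocks for
    Mammalian Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies purifying selection on mammalian mitochondrial
    protein-coding genes and corrects the time dependence it induces in the
    molecular clock. Provides exhaustive single-nucleotide substitution
    enumeration and classification under the vertebrate mitochondrial genetic
    code, parsimony mapping of mutations onto rooted intraspecific trees,
    per-node rho tree-depth statistics (overall protein-coding and
    synonymous-only), pathogenicity-score class comparisons and the
    exponential pathogenicity-selection-constant fit, node agglomeration with
    a Gompertz fit of the synonymous proportion versus rho, selection-corrected
    and synonymous clock dating with maximum-likelihood rate presets, and a
    seeded synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
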