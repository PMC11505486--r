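Package: evorate
Title: Gene Evolutionary Rate, Protein Composition, and Life-History Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Relates a gene's evolutionary rate and its protein's amino-acid
    composition to species life-history traits (maximal reported lifespan,
    adult body weight, longevity quotient). Implements pairwise dN/dS
    estimation by Nei-Gojobori fractional site counting with pathway-averaged
    difference counts and Jukes-Cantor correction, a per-species median-omega
    gene characteristic relative to a taxon's orthologs, ordinary
    least-squares trait association, per-amino-acid composition correlation,
    protein-domain consensus with radical-substitution classification under a
    six-group physicochemical scheme, and longevity-quotient group
    comparisons. Ships seeded synthetic-study generators (codon substitution
    simulator, planted trait models, planted domain deviations) so the whole
    pipeline is testable end to end without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
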