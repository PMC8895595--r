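Package: depositcomp
Title: Composition-Based Identification of Insoluble Deposit Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate components of insoluble protein
    deposits (intranuclear inclusions, aggregates) from amino-acid analysis of
    hydrolyzed fractions. Models acid-hydrolysis chemistry (Gln/Glu and Asn/Asp
    channel pooling, tryptophan loss under HCl), computes residue-count
    compositions of proteins and mixtures, detects the enriched amino-acid
    channel in case versus control hydrolysates, ranks proteomics candidates by
    their content of that channel, compares composition profiles, estimates the
    mixture fraction of a candidate, and annotates low-complexity and
    compositionally biased regions. Includes a seeded synthetic-data generator
    (background proteome plus a spiked tandem-repeat protein) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
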