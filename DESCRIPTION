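Package: crisprE
Title: Gene Essentiality Testing from CRISPR/Cas9 Clonal Editing Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls and classifies CRISPR/Cas9-induced alleles from clonal
    amplicon sequences or pre-called variant tables, collapses sibling clones
    into independent editing events, and quantifies gene essentiality from the
    selective depletion of frameshift alleles among surviving clones: the exact
    all-in-frame null probability, a one-sided exact frameshift-deficit test,
    and an essentiality score E with a Clopper-Pearson confidence interval.
    Includes a clonal non-homologous end joining (NHEJ) outcome simulator with
    configurable indel spectra, sibling clones, sequencing failures and
    viability selection, for power and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
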