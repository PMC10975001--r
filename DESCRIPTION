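Package: hausflow
Title: Parasite-Host Information Exchange Analysis from Four-Compartment
    Omics Designs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for root hemiparasite / host systems sampled
    in four compartments (intact parasite root TH, parasite chimera THC,
    host chimera PC, intact host root P). Implements differential-metabolite
    screening by OPLS-DA variable importance in projection combined with
    fold change, presence/absence classification of transferred metabolites
    and FPKM-threshold detection of mobile mRNAs with transfer direction,
    unigene origin assignment against two reference genomes (BLAST tabular
    input or a built-in canonical k-mer classifier), selection of
    haustoria-formation-associated genes, Pearson gene-metabolite
    correlation networks with edge-table/SIF export, and a synthetic
    four-compartment experiment generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
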