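Package: tcrkit
Title: Detection and Quantification of Termination Codon Readthrough
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying termination codon
    readthrough (TCR) from transcript sequences, ribosome-profiling
    footprint libraries, and dual-luciferase reporter assays. Locates the
    first downstream in-frame stop codon of a transcript, extracts and
    translates the inter-stop-codon region (ISR), and scores cross-species
    conservation of the predicted C-terminal extension peptide; assigns
    exact-matching ribosome footprints to transcript regions with
    configurable ISR window offsets and compares per-nucleotide read
    densities between the ISR and the distal 3'UTR; computes percent
    readthrough from firefly/Renilla luciferase ratios together with
    delta-delta-Ct and densitometry normalisation helpers. A synthetic-data
    module generates reproducible transcripts, footprint libraries,
    luciferase tables, and ortholog peptide panels with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
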