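Package: organellr
Title: Organelle Genome Graph Resolution, Repeat Landscapes and
    Plastid-Mitochondrial Transfer Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for finishing and comparing plant organelle genomes.
    Resolves repeat-induced double-bifurcation structures in a unitig
    assembly graph with long-read support and reconstructs the circular
    master molecule as an Eulerian walk; detects microsatellites
    (MISA-style thresholds), dispersed repeats (forward, palindromic,
    reverse, with mismatches) and tandem arrays; recovers the
    quadripartite LSC-IR-SSC plastome structure and compares assemblies
    up to SSC inversion; finds homologous fragments between plastome and
    mitogenome by seeded local alignment and classifies their origin
    (vertical inheritance versus plastid-to-mitochondrion transfer)
    against an outgroup pair; ranks hypervariable intergenic spacers by
    Kimura 2-parameter distance and selects a minimal diagnostic
    SNP/indel set that discriminates a species panel. Includes a
    synthetic-data generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
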