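Package: numtsieve
Title: Discriminating Mitochondrial Heteroplasmy from Nuclear Insertions
    of Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether low-frequency intra-individual
    polymorphism observed on a plant mitochondrial genome reflects true
    heteroplasmy or cross-mapped reads from nuclear insertions of
    mitochondrial DNA (numts). Partitions an mtDNA reference into eight
    homology categories (self-repeat, nuclear-homologous,
    plastid-homologous), scans 50-bp tiles against multiple nuclear
    assemblies to expose presence/absence polymorphism of numts, extracts
    polymorphic sites from per-site base compositions with
    fraction-and-read-count thresholds, phases linked variant alleles from
    spanning reads, matches variant haplotypes against candidate numts,
    and genotypes an in-silico PCR-RFLP marker with an exact multinomial
    segregation test. A seeded simulator generates mitochondrial, plastid
    and nuclear genomes with planted repeats, numts and heteroplasmic
    sites, plus copy-ratio-weighted paired-end reads, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    methods
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
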