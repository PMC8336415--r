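Package: clockscape
Title: Genome Landscapes of Regional Molecular Clock Rate Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window exome landscapes of protein evolutionary rates
    across mammalian genomes. Computes pairwise protein divergence from
    global alignments, fits the genome-wide molecular clock (PDav% = kav * t),
    normalizes per-gene divergence to the genome average (nPD% = k/kav),
    builds 101-gene sliding-window landscapes of GC%, GARP% and nPD% on a
    chosen gene order, detects regionally accelerated genes against a
    randomized-gene-order null (mean + 3 SD threshold), quantifies
    subtelomeric enrichment, and classifies subtelomere concordance of
    accelerated genes between two genome orders. Includes a synthetic-data
    generator emulating a 16-species, ~15,727-gene study design so the whole
    pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
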