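Package: depthdiv
Title: Depth-Layer Diversity and Functional Profiling of Ocean Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of shotgun-metagenome read classifications
    across ocean depth layers (surface, deep chlorophyll maximum, and
    mesopelagic). Reads Kaiju-style per-read taxonomic classification tables,
    aggregates them into rank-resolved taxonomic profiles, computes per-sample
    abundance and normalized Shannon-Wiener diversity indices, clusters samples
    by UPGMA with the Mojena stopping rule, compares depth layers with Wilcoxon
    rank-sum tests under Bonferroni correction, and profiles Gene Ontology term
    frequencies and layer-exclusive term sets. Includes a seeded synthetic
    multi-station community generator with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
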