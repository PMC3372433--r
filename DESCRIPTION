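Package: synmapr
Title: Comparative Mapping of Conserved Syntenic Segments Between Genetic
    Maps and Physical Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved syntenic segments (CSS) between genetic maps
    (marker positions in centiMorgans) and physical genomes (base-pair
    coordinates) by distance-constrained chaining of single-locus orthologous
    markers. Includes an E-value cascade for ortholog assignment from BLAST
    tabular hits with single-locus filtering, block summary statistics,
    three-way block triangulation on a shared reference genome, BAC-scale
    gene-order microsynteny classification, and a genome-rearrangement
    simulator (inversions, reciprocal translocations, fusions, fissions,
    marker loss, paralog noise) that provides ground-truthed synthetic inputs
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    jsonlite,
    readr,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
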