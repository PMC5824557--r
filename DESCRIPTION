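Package: sibmap
Title: Full-Sib Linkage Maps, Consensus Merging and Synteny Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction of sex-specific, family and consensus genetic
    linkage maps from full-sib (CP) outcross SNP genotypes, and comparative
    mapping against assembled genomes. Implements segregation typing and
    distortion filtering, co-segregation binning, two-point recombination
    fraction estimation by EM with simultaneous linkage-phase inference,
    LOD-threshold linkage grouping, marker ordering with a ripple search,
    map-distance computation (Kosambi or Haldane), conflict-aware consensus
    merging of family maps by linear programming minimizing mean absolute
    error, detection of syntenic blocks from sequence-similarity anchors,
    and placement of external features (QTL markers, transcripts) onto the
    map by interpolation between syntenic flanking loci. A simulator for
    full-sib crosses and rearranged comparison genomes with known ground
    truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    boot,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
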