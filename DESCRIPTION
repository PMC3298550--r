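Package: achiasmap
Title: Linkage Mapping and Comparative Genomics for Achiasmatic F2 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of gene-based SNP linkage maps for
    species in which one sex does not recombine, such as the copepod
    Tigriopus californicus. Provides a synthetic-cross simulator (F2
    intercross and non-recombinant backcross under female achiasmy),
    two-point recombination-fraction and LOD estimation under the
    achiasmatic F2 likelihood, sex-specific recombination estimation,
    Kosambi map functions, single-linkage grouping and SARF/2-opt marker
    ordering, segregation-distortion and implied-female-recombination
    marker QC, map summary statistics (corrected length, genome coverage,
    recombination rate), synonymous/nonsynonymous SNP classification
    against transcript coding sequences, and a permutation test for shared
    macrosynteny with reference genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
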