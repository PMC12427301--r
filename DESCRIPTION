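Package: karyevol
Title: Karyotype Morphometrics, Homology Matching, and Chromosomal
    Rearrangement Parsimony
Version: 0.1.0
Authors@R:
    person("karyevol", "developers", email = "karyevol@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative cytogenetics of taxa described by
    chromosome morphometrics. Classifies chromosome pairs into Levan
    shape classes (metacentric, submetacentric, subtelocentric,
    telocentric) from centromeric indices, summarizes karyotype formulas,
    matches homologous pairs between karyotypes by
    standard-deviation-scaled minimum-cost assignment, reconstructs
    ancestral karyotypes and minimal inversion/translocation scenarios on
    a phylogeny by small parsimony, and re-implements uncorrected
    p-distance, neighbour joining, and bootstrap support for mitochondrial
    marker alignments. Includes generators for synthetic morphometric
    tables, karyotype evolution along a tree, and Jukes-Cantor sequence
    alignments, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
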