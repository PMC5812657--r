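Package: karyevo
Title: Karyotype Morphometrics and Parsimony Ancestral-State Analysis of
    Chromosome Evolution in Cophomantine Treefrogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytogenetic character analysis in a phylogenetic
    framework: centromeric-index morphometrics and chromosome morphology
    classification, fundamental-number and relative-length arithmetic,
    idiogram geometry, coding of basic chromosome number and NOR-bearing
    pair as unordered phylogenetic characters with explicit homology rules,
    and Hartigan-style unordered-parsimony ancestral-state reconstruction
    (tree length, MPR state sets, branch transformations, synapomorphy and
    ambiguity reports) on rooted, possibly multifurcating trees. Ships a
    curated karyotype dataset for the Neotropical treefrog tribe
    Cophomantini (genera Aplastodiscus, Boana, Bokermannohyla, Hyloscirtus,
    and Myersiohyla) together with a condensed reference phylogeny, plus
    simulators for noisy karyotype measurements and discrete-character
    histories used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
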