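Package: tcmariner
Title: Characterisation of Tc1/mariner DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterising Tc1/mariner (ITm) DNA transposons:
    homology-hit retention filtering with iterative query expansion,
    sequence-to-profile alignment for locating the DDD/E catalytic triad,
    family assignment from triad spacing signatures, element structure
    annotation (transposase ORFs, terminal inverted repeats, TA target-site
    duplications), genome copy-number census, neighbor-joining phylogenies
    with bootstrap support and outgroup rooting, transposon-versus-host
    tanglegram congruence, and a horizontal transposon transfer candidate
    screen. Synthetic-data generators with machine-readable truth tables
    allow the whole pipeline to be validated end to end without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
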