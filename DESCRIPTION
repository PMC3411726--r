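Package: napadduct
Title: Annotation and Site Localization of Naphthalene Metabolite Peptide
    Adducts from High-Resolution MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing covalent adducts of reactive naphthalene
    metabolites (the 1,2-epoxide, the diol epoxide, and the 1,2- and
    1,4-naphthoquinones) on peptides from high-resolution tandem mass spectra.
    Computes monoisotopic masses and singly-protonated precursor and b/y
    fragment ions for adduct placements, matches observed peak lists within a
    ppm tolerance, infers the adducted residue (or N-terminal amine) from which
    fragments do and do not carry the mass shift, and quantifies
    pseudo-first-order depletion of the unadducted peptide from selected-ion
    monitoring time courses. A seeded simulator generates ground-truthed CID
    spectra and depletion curves so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
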