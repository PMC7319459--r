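Package: becorrect
Title: Matching Base Editors to Precise and Synonymous Corrections of Point Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Given a pathogenic single-nucleotide variant in a coding
    sequence, searches a registry of 26 published CRISPR base editors (17
    cytosine and 9 adenine deaminase fusions, plus user-defined editors)
    for PAM placements that put the variant inside an activity window,
    deterministically simulates the resulting deamination edit on either
    strand, and classifies each outcome as a precise correction of the DNA
    or as one of three synonymous corrections of the translated coding
    sequence, including transversion-derived mutations rescued only at the
    protein level. Includes cohort-level repairability statistics, a
    codon-degeneracy enumeration of recoverable amino-acid substitutions,
    and a seeded synthetic-fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
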