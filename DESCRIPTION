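Package: sagetags
Title: SAGE Tag Extraction, Audic-Claverie Differential Expression, and
    qPCR Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing two Serial Analysis of Gene Expression
    (SAGE) tag libraries. Extracts canonical 21-bp tags from concatemer
    clone sequences (CATG anchoring enzyme, MmeI tagging enzyme), counts
    tags per library, detects differentially represented tags with the
    Audic-Claverie conditional-probability test and a library-size
    corrected ratio statistic with banded significance reporting, and
    validates selected genes with efficiency-corrected qPCR relative
    quantification including a label-permutation significance test.
    Includes a fully seeded synthetic-data generator producing paired tag
    libraries with planted differential expression, concatemer FASTA
    realizing those libraries, and qPCR amplification curves with known
    efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
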