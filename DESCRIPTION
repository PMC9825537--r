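Package: quatclust
Title: Clustering Protein Quaternary-Structure Assemblies Across Independent Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects chain-chain interfaces in protein assemblies, reduces each
    assembly to its unique connecting interfaces, scores interface similarity
    with a contact-based Q score in a homologous position coordinate, detects
    cyclic and dihedral point-group (pseudo-)symmetry, groups crystallographic
    entries into crystal forms, and clusters assemblies of homologous proteins
    across crystal forms and EM/NMR experiments by a binary similarity test.
    Reports evidence statistics such as the fraction of a protein's crystal
    forms that contain a clustered assembly (R_CF_UNPclus). Includes a
    generator of exact synthetic oligomer fixtures so the full pipeline runs
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
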