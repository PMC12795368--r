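Package: demisp
Title: Screening for Modification-Induced Sequence Permutations in Peptide Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens peptide identifications for isobaric sequence permutations
    induced by deamidation (N to D, Q to E) and N-terminal pyroglutamic acid
    formation, and compares the taxonomic lowest common ancestor (LCA) of each
    permutation against that of the input peptide. Reads Mascot and MaxQuant
    style peptide tables, enumerates every mass-identical permutation under a
    three-stage substitution procedure, resolves LCAs through the Unipept
    pept2lca service or an offline lookup table, classifies alternate
    taxonomies as identical, more specific, less specific or different, and
    flags peptides whose deamidation positions require manual verification.
    Includes a synthetic fixture generator (toy taxonomy, peptide tables,
    offline LCA tables) so the whole pipeline runs without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
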