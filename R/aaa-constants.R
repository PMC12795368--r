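# Package-wide constants (this file loads first).

# The standard 20-letter amino-acid alphabet.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Canonical taxonomic ranks, root-to-leaf order, used to order lineages and
# by the toy-taxonomy generator.
CANONICAL_RANKS <- c(
  "superkingdom", "kingdom", "phylum", "class", "order",
  "family", "genus", "species"
)
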