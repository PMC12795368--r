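# demisp

Screening peptide identifications for **modification-induced sequence
permutations** (MISPs) and the taxonomic conclusions that depend on them.

## Why

Peptide-based taxonomic identification (as in palaeoproteomics / ZooMS
workflows) assigns each peptide a lowest common ancestor (LCA) — the most
specific taxon shared by every protein that contains it. Two common chemical
artefacts undermine this:

- **Deamidation** converts asparagine to aspartic acid (N→D) and glutamine to
  glutamic acid (Q→E), each adding +0.98402 Da. In degraded or ancient samples
  deamidation is pervasive, so search engines allow it as a variable
  modification.
- **N-terminal pyroglutamic acid** formation makes a peptide starting in Q
  indistinguishable by mass from the same peptide starting in E (and vice
  versa) when the complementary deamidation is considered.

Because a deamidated N is *chemically identical* to a genomically encoded D
(and Q to E), a peptide reported as `...N(+0.98)...` may equally well be a
different peptide encoded with D at that position — possibly from a different
taxon. Every such mass-identical re-reading of the sequence is a MISP. If any
MISP maps to a different LCA than the input peptide, the taxonomic claim rests
on correctly localising the deamidation, which deserves manual scrutiny.

`demisp` enumerates all MISPs for each input peptide + modification
combination, resolves their LCAs (live via Unipept `pept2lca`, or from an
offline lookup table), classifies each peptide's alternate taxonomies as
`no_alternate`, `all_identical`, `more_specific`, `less_specific` or
`different`, and flags peptides whose deamidation positions need manual
verification. It does not replace manual validation (ion coverage, BLAST); it
tells you where that effort is needed.

## The permutation model

For an input sequence with `d` allowed deamidations, permutations are built in
three stages:

1. **Forward (stage 1):** every subset of the N/Q positions of size ≤ `d` is
   rewritten N→D / Q→E (the reported deamidations may sit at any of the
   candidate sites).
2. **Reverse (stage 2):** independently, every subset of the D/E positions is
   rewritten D→N / E→Q (an encoded D/E could instead be a deamidated N/Q in
   the true peptide).
3. **Pyro-Glu:** if the peptide carries an N-terminal `Gln->pyro-Glu`
   (`Glu->pyro-Glu`) modification, each variant is doubled with position 1
   swapped Q↔E; the consumed terminal residue is excluded from stages 1–2.

Counts are *identity-inclusive*: whenever a peptide has at least one
substitutable site, the unchanged sequence itself is counted as one of its
permutations (it is one of the possible readings). The closed form is

```
count = [ Σ_{k=0..min(d, |NQ|)} C(|NQ|, k) ] × 2^|DE| × (2 if pyro-Glu)
```

All permutations are isobaric with the input: the base-mass difference is
always an integer multiple of 0.98402 Da that cancels against the modification
mass.

## Worked example

```r
library(demisp)

prof <- parse_modifications("Deamidated (NQ); Gln->pyro-Glu")
pset <- enumerate_misps("QYDNGNQIDLQELK", prof)
length(pset$permutations)
#> [1] 80
head(misp_sequences(pset), 4)
#> [1] "EYDDGNQIDLQELK" "EYDDGNQIDLQQLK" "EYDDGNQINLQELK" "EYDDGNQINLQQLK"

sm <- substitutable_sites("QYDNGNQIDLQELK", prof)
expected_count(sm, prof$deamidation_count)
#> [1] 80
```

A full screen against an offline LCA table (here using the bundled synthetic
fixture generator, which builds a toy taxonomy, a peptide table and a matching
LCA table so everything runs without network access):

```r
fx <- generate_fixture(fixture_spec(seed = 1, n_peptides = 8), dir = tempdir())
cfg <- run_config(fx$paths[["peptides"]], backend = "offline",
                  offline_table_path = fx$paths[["lca_table"]],
                  out_dir = tempdir(), stem = "demo")
res <- run_screen(cfg)
#> [demisp] read 8 peptide rows from .../peptides.csv
#> [demisp] generated 202 permutations (identity-inclusive) for 8 peptides
#> [demisp] queried 202 distinct sequences (0 unresolved)
#> [demisp] 8 of 8 peptides have permutations; 5 have alternate LCAs
#> [demisp] wrote demo_results.csv, demo_permutations.csv, demo_results.json ...
```

First rows of `demo_results.csv`:

```
   input_sequence     modifications total_misps      category manual_check_required
1     TPEVDDEALEK                            32     different                 FALSE
2 NNGKTEYGLFQINNK 3 Deamidated (NQ)          52     different                  TRUE
3 MWHQHMMVQQDHHCP   Deamidated (NQ)           8 all_identical                 FALSE
```

Outputs are a per-peptide results CSV, a per-permutation CSV (every MISP with
its LCA where available) and a nested JSON; all three are byte-stable across
runs. A command-line wrapper with the same options lives at
`inst/scripts/demisp.R` (subcommands `screen` and `simulate`).

Live Unipept screening uses the same interface with
`run_config(..., backend = "unipept")`; requests are batched, retried with
exponential backoff, and length-filtered to Unipept's accepted range, with
unresolved peptides reported rather than dropped.

## The manual-check flag

A peptide is flagged (`manual_check_required`) when all three hold:

1. the number of reported deamidations is smaller than the number of
   deamidatable positions (so the placement is ambiguous),
2. at least one deamidation is reported, and
3. its permutations resolve to at least two distinct LCAs (so the placement
   matters).

## Testing

```r
testthat::test_dir("tests/testthat", package = "demisp",
                   load_package = "installed")
```

The suite includes property-based comparisons against an independent
brute-force enumerator, mass-invariant checks, a taxonomy-relation oracle and
end-to-end determinism checks. One acceptance test expects a curated benchmark
peptide list at `inst/extdata/benchmark_peptides.csv`; that table is an
external download that is not redistributed here, so the test fails until the
file is supplied.

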