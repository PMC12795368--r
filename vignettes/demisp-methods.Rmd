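---
title: "Methods: modification-induced sequence permutations and their taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modification-induced sequence permutations and their taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demisp)
```

## The problem being modelled

Peptide-mass-based taxonomic identification assigns each peptide its lowest
common ancestor (LCA): the most specific taxon shared by all proteins
containing that exact sequence. Deamidation (N→D, Q→E, +0.98402 Da each) and
N-terminal pyroglutamic acid formation make several *different* sequences
indistinguishable by mass from the reported one. Each such mass-identical
alternative reading is a modification-induced sequence permutation (MISP). If
a MISP has a different LCA than the input peptide, the taxonomic assignment
depends on the correctness of the deamidation localisation, which fragment
spectra often cannot settle on their own.

`demisp` makes this ambiguity explicit: it enumerates the MISPs, resolves
their LCAs and reports where the taxonomy is robust and where it is not. It is
a screening tool; it deliberately does not attempt probabilistic modification
scoring, spectrum rescoring or automatic verification.

## The permutation model

For a sequence and a modification profile with `d` deamidations, the
enumeration has three stages:

- **Stage 1 (forward).** Deamidation may sit at any N/Q position, so every
  subset of those positions of size 0…`d` is rewritten N→D / Q→E.
- **Stage 2 (reverse).** Any encoded D/E could instead be a deamidated N/Q of
  a different underlying peptide, so every subset of the D/E positions
  (positions in the *original* sequence; the two stages act on disjoint
  sites) is independently rewritten D→N / E→Q.
- **Stage 3 (pyro-Glu).** An N-terminal pyro-Glu makes a leading Q and a
  leading E isobaric, so the variant set is doubled with position 1 swapped
  Q↔E. The consumed terminal residue is excluded from stages 1–2.

Every combination of a stage-1 choice and a stage-2 choice (times the
pyro-Glu doubling) is a distinct sequence, so the count has a closed form:

$$\text{count} \;=\; \Big(\sum_{k=0}^{\min(d,\,s_1)} \binom{s_1}{k}\Big)
\times 2^{s_2} \times (2\ \text{if pyro-Glu})$$

with $s_1$ the number of eligible N/Q sites and $s_2$ the number of eligible
D/E sites. The engine enumerates the same set explicitly and the test suite
checks set-equality against an independent brute-force enumerator as well as
the closed form.

### The identity-inclusion convention

Counts are *identity-inclusive*: if a peptide has any substitutable site at
all, the unchanged sequence counts as one of its permutations, because it is
one of the possible readings of the observed mass. A peptide with no
substitutable site has zero permutations. Concretely, "has substitutable
sites" means: (`d` ≥ 1 and ≥ 1 N/Q site) or ≥ 1 D/E site or an applicable
pyro-Glu. Downstream taxonomic comparisons exclude the identity sequence —
only genuinely alternate sequences can produce alternate LCAs.

```{r}
profile <- parse_modifications("3 Deamidated (NQ)")
pset <- enumerate_misps("FQSEEQQQTEDELQDKIHPFAQTQ", profile)
length(pset$permutations)
```

This 24-residue peptide has 12 N/Q sites and 6 D/E sites, giving
$(\binom{12}{0}+\binom{12}{1}+\binom{12}{2}+\binom{12}{3}) \times 2^6 = 64
\times 64 = 4096$ readings — a concrete reminder that heavily deamidated
peptides are weak taxonomic evidence on their own.

### Mass invariants

Residue masses are monoisotopic. Each permutation's base mass differs from
the input's by an integer multiple of 0.98402 Da (the D−N and E−Q mass
difference), the integer being exactly the net number of forward minus
reverse substitutions; with the variable-modification masses applied, input
and permutation coincide. `isobaric_shift_multiple()` verifies this per
permutation and the suite asserts it over thousands of random peptides with a
tolerance of 1e-3 Da.

### Combinatorial safety

The number of permutations is exponential in the site count, so
`enumerate_misps()` takes a `cap` (default 1,000,000). Generation is bounded:
subsets are produced in lexicographic order and allocation never exceeds the
cap; beyond it the set is truncated with a warning (or an error with
`strict = TRUE`).

## Input handling

Two table dialects are auto-detected from the header: `Sequence` /
`Modifications` and `pep_seq` / `pep_var_mod`. Modification strings are
matched case-insensitively against the deamidation spellings
(`Deamidated (NQ)`, `2 x Deamidation (NQ)`, …) and the pyro-Glu spellings
(`Gln->pyro-Glu`, `Glu->pyro-Glu`); multiple deamidation tokens sum.
Unrecognised modifications are retained verbatim in an `ignored_mods` field —
they are assumed mass-irrelevant to the N/Q/D/E readings and do not silently
disappear. A pyro-Glu flag contradicting the first residue is cleared with a
warning during validation.

## LCA resolution

Two backends share one interface (`fetch_lcas()`):

- **Offline:** a five-column TSV (`peptide`, `taxon_id`, `taxon_name`,
  `taxon_rank`, `lineage`, with lineage as pipe-separated
  `rank:taxon_id:name` triples). Deterministic and network-free; this is the
  backend used by the whole test suite.
- **Unipept:** the public `pept2lca` API. Queries are deduplicated, batched
  (default 90 peptides per request), retried up to `max_retries` times with
  exponential backoff (`backoff_base` × 2^(attempt−1) seconds), and
  length-filtered to 5–50 residues. Filtered or exhausted peptides come back
  with status `unresolved` and a reason rather than vanishing. The transport
  and the sleep function are injectable, so all retry/batching behaviour is
  unit-tested without a network.

The result keyset always equals the input set; statuses are `match`,
`no_match` or `unresolved`.

## Classifying alternate taxonomies

Lineages are compared by taxon-id prefix ancestry. Against the input
peptide's LCA, each permutation LCA is `identical`, `more_specific` (a
descendant), `less_specific` (an ancestor) or `different` (disjoint). The
per-peptide category is:

- `no_alternate` — no permutation had an LCA;
- `all_identical` — every permutation LCA equals the input's;
- `less_specific` — *at least one* permutation LCA is an ancestor of the
  input's. This overrides everything else: a single less-specific reading
  means the data cannot exclude the broader taxon;
- otherwise `different` if any disjoint LCA exists, else `more_specific`.

## The manual-check flag

`needs_manual_check()` is the conjunction of three conditions: the reported
deamidation count is smaller than the number of deamidatable residues (an
N-terminal Q consumed by pyro-Glu does not count), at least one deamidation
is reported, and the permutations resolve to at least two distinct LCAs.
Peptides failing any conjunct either have unambiguous placement or placement
that cannot change the conclusion.

## The fixture generator

`generate_fixture()` exists so the full pipeline — ingest, enumeration, LCA
lookup, classification, reporting — can be exercised deterministically and
offline. It emulates the *shape* of a real screen, not real biology:

- a balanced toy taxonomy (`taxonomy_shape`, default depth 4 × branching 3)
  with canonical ranks and breadth-first taxon ids;
- random peptides (default 40, lengths 7–15, N/Q/D/E site density 0.35,
  0–3 deamidations, pyro-Glu probability 0.15) plus planted scenarios: a
  sibling-genus `different` case, a deliberately under-specified
  `manual_flag` case, and a rotation covering every category;
- an offline LCA table whose leaf assignments make each intended LCA the true
  tree LCA, and a manifest of expected outcomes computed from the closed-form
  count and an independent tree-ancestry oracle — *not* from the pipeline —
  so end-to-end tests have a non-circular expected answer.

Peptide sequences, taxon names and lineages are synthetic; the generator does
not emulate real digests, protein databases, spectra or fragment evidence.
Default sizes keep each fixture file small and fast to regenerate; all files
are plain text.

## Numerical and formatting choices

- Monoisotopic residue masses are stored to 5 decimal places; the deamidation
  shift is 0.98402 Da; mass checks use an absolute tolerance of 1e-3 Da.
- Dataset statistics follow fixed conventions so outputs are reproducible:
  the median of an even-length count vector is the lower middle value, a
  modal tie is broken toward the smallest count, and the mean is truncated
  (not rounded) to one decimal, with a 1e-9 epsilon so exact tenths never
  truncate downward through floating-point error. Zero-permutation peptides
  are included in all statistics.
- Output files are byte-stable: fixed row ordering, fixed float formatting,
  writes go to a temporary file that is atomically renamed.

## Limitations

- The model covers deamidation and N-terminal pyro-Glu only; other
  substitutions that are near-isobaric at low resolution (e.g. Ala↔Ser
  against hydroxylation) are out of scope.
- Enumeration treats all site subsets as equally plausible; no spectral or
  probabilistic weighting is applied.
- Live results depend on the Unipept database version current at query time;
  LCAs for the same peptide can legitimately drift between database releases,
  which is why reproducibility claims attach to the offline backend.
- Flagged peptides still require manual verification (fragment coverage,
  sequence searches); the flag marks where that work is needed, it does not
  do it.
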