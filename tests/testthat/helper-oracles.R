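# Shared test helpers: profile builders, a brute-force permutation oracle,
# and small toy-taxonomy conveniences.

make_profile <- function(d = 0L, pyro = c("none", "Q", "E")) {
  pyro <- match.arg(pyro)
  structure(
    list(deamidation_count = as.integer(d),
         pyroglu_from_q = identical(pyro, "Q"),
         pyroglu_from_e = identical(pyro, "E"),
         ignored_mods = character(0)),
    class = "demisp_mod_profile"
  )
}

# Brute-force oracle: try every letter assignment at the exchangeable
# positions and keep exactly those reachable under the stage rules, working
# from the rules as stated rather than from the engine's enumeration order.
brute_force_misps <- function(sequence, d, pyro = c("none", "Q", "E")) {
  pyro <- match.arg(pyro)
  letters_in <- strsplit(sequence, "")[[1]]
  n <- length(letters_in)
  swap <- c(N = "D", Q = "E", D = "N", E = "Q")

  pyro_active <- (pyro == "Q" && letters_in[1] == "Q") ||
    (pyro == "E" && letters_in[1] == "E")
  stage1 <- which(letters_in %in% c("N", "Q"))
  stage2 <- which(letters_in %in% c("D", "E"))
  if (pyro == "Q" && pyro_active) stage1 <- setdiff(stage1, 1L)
  if (pyro == "E" && pyro_active) stage2 <- setdiff(stage2, 1L)

  has_sites <- (d >= 1 && length(stage1) >= 1) || length(stage2) >= 1 ||
    pyro_active
  if (!has_sites) return(character(0))

  variable <- sort(unique(c(
    if (d >= 1) stage1 else integer(0),
    stage2,
    if (pyro_active) 1L else integer(0)
  )))
  if (length(variable) == 0) return(sequence)

  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(variable)))
  out <- character(0)
  for (gi in seq_len(nrow(grid))) {
    flips <- variable[unlist(grid[gi, ])]
    cand <- letters_in
    cand[flips] <- swap[cand[flips]]
    n_stage1 <- sum(flips %in% stage1)
    if (n_stage1 > d) next
    out <- c(out, paste(cand, collapse = ""))
  }
  sort(unique(out))
}

random_test_peptide <- function(len, alphabet = c("A", "N", "Q", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a three-level lineage chain used by taxonomy unit tests
chain_lca <- function(peptide, ids, names_, ranks = NULL) {
  if (is.null(ranks)) {
    ranks <- c("superkingdom", "kingdom", "phylum", "class", "order",
               "family", "genus", "species")[seq_along(ids)]
  }
  n <- length(ids)
  lca_result(peptide, ids[n], names_[n], ranks[n],
             lineage(ranks, ids, names_))
}

# tiny offline table written to a temp file, from (peptide -> taxon id) in a
# toy taxonomy
write_toy_table <- function(taxonomy, assignment, path = tempfile()) {
  results <- lapply(names(assignment), function(p) {
    toy_lca_result(taxonomy, p, assignment[[p]])
  })
  write_offline_table(results, path)
  path
}
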