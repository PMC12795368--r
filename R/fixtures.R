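#' Build a deterministic toy taxonomy
#'
#' A balanced rooted tree whose levels carry the canonical ranks in
#' ancestor order (level 0 = superkingdom, ...). Node ids are assigned
#' breadth-first starting at 1 (the root), so the tree is a pure function of
#' its shape; `seed` is accepted for interface symmetry with the other
#' generators but does not alter the topology.
#'
#' @param depth Number of levels (>= 2, <= 8).
#' @param branching Children per internal node (>= 1).
#' @param seed Unused for topology; kept for a stable generator interface.
#' @return A `demisp_toy_taxonomy`: data frame `nodes` (`taxon_id`, `name`,
#'   `rank`, `parent_id`; root parent is NA) plus `root_id`, `depth`,
#'   `branching`.
#' @export
build_toy_taxonomy <- function(depth, branching, seed = 1L) {
  stopifnot(depth >= 2, depth <= length(CANONICAL_RANKS), branching >= 1)
  ids <- integer(0); parents <- integer(0); ranks <- character(0)
  level_nodes <- 1L
  next_id <- 2L
  ids <- 1L; parents <- NA_integer_; ranks <- CANONICAL_RANKS[1]
  for (lev in seq_len(depth - 1)) {
    children <- integer(0)
    for (p in level_nodes) {
      kids <- seq.int(next_id, length.out = branching)
      next_id <- next_id + branching
      ids <- c(ids, kids)
      parents <- c(parents, rep(p, branching))
      ranks <- c(ranks, rep(CANONICAL_RANKS[lev + 1], branching))
      children <- c(children, kids)
    }
    level_nodes <- children
  }
  nodes <- data.frame(
    taxon_id = ids,
    name = paste0("taxon_", ids),
    rank = ranks,
    parent_id = parents,
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, root_id = 1L, depth = depth, branching = branching),
    class = "demisp_toy_taxonomy"
  )
}

.ancestor_chain <- function(taxonomy, taxon_id) {
  nodes <- taxonomy$nodes
  if (!taxon_id %in% nodes$taxon_id) {
    stop("unknown taxon ", taxon_id, call. = FALSE)
  }
  chain <- integer(0)
  cur <- taxon_id
  while (!is.na(cur)) {
    chain <- c(cur, chain)
    cur <- nodes$parent_id[match(cur, nodes$taxon_id)]
  }
  chain  # root ... taxon
}

#' Lowest common ancestor in a toy taxonomy
#'
#' @param taxonomy A `demisp_toy_taxonomy`.
#' @param taxa Non-empty vector of taxon ids present in the taxonomy.
#' @return The deepest node that is an ancestor-or-self of every input.
#' @export
tree_lca <- function(taxonomy, taxa) {
  stopifnot(length(taxa) >= 1)
  chains <- lapply(taxa, function(t) .ancestor_chain(taxonomy, t))
  k <- min(lengths(chains))
  lca <- chains[[1]][1]
  for (i in seq_len(k)) {
    step <- vapply(chains, `[`, 0L, i)
    if (all(step == step[1])) lca <- step[1] else break
  }
  lca
}

#' Lineage of a toy-taxonomy node
#'
#' @param taxonomy A `demisp_toy_taxonomy`.
#' @param taxon_id A node id.
#' @return A `demisp_lineage` root-to-node.
#' @export
toy_lineage <- function(taxonomy, taxon_id) {
  chain <- .ancestor_chain(taxonomy, taxon_id)
  idx <- match(chain, taxonomy$nodes$taxon_id)
  lineage(taxonomy$nodes$rank[idx], chain, taxonomy$nodes$name[idx])
}

#' LCA result for a peptide assigned to a set of toy-taxonomy leaves
#'
#' @param taxonomy A `demisp_toy_taxonomy`.
#' @param peptide Peptide sequence.
#' @param taxa Taxon ids of the proteins "containing" the peptide.
#' @return A `demisp_lca_result` at `tree_lca(taxonomy, taxa)`.
#' @export
toy_lca_result <- function(taxonomy, peptide, taxa) {
  t <- tree_lca(taxonomy, taxa)
  idx <- match(t, taxonomy$nodes$taxon_id)
  lca_result(peptide, t, taxonomy$nodes$name[idx], taxonomy$nodes$rank[idx],
             toy_lineage(taxonomy, t))
}

.leaves_under <- function(taxonomy, node) {
  nodes <- taxonomy$nodes
  is_leaf <- !nodes$taxon_id %in% nodes$parent_id
  out <- integer(0)
  frontier <- node
  while (length(frontier) > 0) {
    out <- c(out, frontier[is_leaf[match(frontier, nodes$taxon_id)]])
    frontier <- nodes$taxon_id[nodes$parent_id %in% frontier &
                                 !is.na(nodes$parent_id)]
  }
  sort(out)
}

# a leaf set whose tree LCA is exactly `target`: the target itself if it is
# a leaf, else one leaf from each of two distinct children subtrees
.leafset_with_lca <- function(taxonomy, target) {
  leaves <- .leaves_under(taxonomy, target)
  if (length(leaves) == 1 && leaves[1] == target) return(target)
  children <- taxonomy$nodes$taxon_id[
    !is.na(taxonomy$nodes$parent_id) & taxonomy$nodes$parent_id == target
  ]
  if (length(children) < 2) {
    # unary chain: no leaf set below has LCA exactly at target; fall back to
    # the target itself acting as a terminal taxon
    return(target)
  }
  c(min(.leaves_under(taxonomy, children[1])),
    min(.leaves_under(taxonomy, children[2])))
}

#' Fixture specification
#'
#' Defaults describe a small but structured screening scenario: 40 peptides
#' of tryptic-like length 7-15, with N/Q/D/E oversampled to 35% of residues
#' so that multi-site permutation logic is exercised, detected deamidation
#' counts between 0 and 3 (the range spanned by published ancient-peptide
#' searches), N-terminal pyroglutamate on 15% of eligible peptides, and a
#' depth-4, 3-ary toy taxonomy.
#'
#' @param seed Integer RNG seed.
#' @param n_peptides Number of generated peptides.
#' @param length_range Min/max peptide length.
#' @param site_density Expected fraction of N/Q/D/E residues.
#' @param deamidation_range Candidate detected-deamidation counts.
#' @param pyroglu_probability Probability of planting an N-terminal
#'   pyroglutamate modification.
#' @param taxonomy_shape `c(depth, branching)` of the toy taxonomy.
#' @return A `demisp_fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_peptides = 40L,
                         length_range = c(7L, 15L), site_density = 0.35,
                         deamidation_range = 0:3,
                         pyroglu_probability = 0.15,
                         taxonomy_shape = c(4L, 3L)) {
  stopifnot(length(length_range) == 2, length_range[1] >= 2,
            site_density >= 0, site_density <= 1,
            pyroglu_probability >= 0, pyroglu_probability <= 1,
            length(deamidation_range) >= 1)
  structure(
    list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
         length_range = as.integer(length_range),
         site_density = site_density,
         deamidation_range = as.integer(deamidation_range),
         pyroglu_probability = pyroglu_probability,
         taxonomy_shape = as.integer(taxonomy_shape)),
    class = "demisp_fixture_spec"
  )
}

.SITE_LETTERS <- c("N", "Q", "D", "E")
.OTHER_LETTERS <- setdiff(AA_ALPHABET, .SITE_LETTERS)

.random_peptide <- function(len, site_density) {
  is_site <- stats::runif(len) < site_density
  letters_out <- character(len)
  letters_out[is_site] <- sample(.SITE_LETTERS, sum(is_site), replace = TRUE)
  letters_out[!is_site] <- sample(.OTHER_LETTERS, sum(!is_site),
                                  replace = TRUE)
  paste(letters_out, collapse = "")
}

.mods_string <- function(d, pyro_dir) {
  parts <- character(0)
  if (d == 1) parts <- "Deamidated (NQ)"
  else if (d > 1) parts <- paste(d, "Deamidated (NQ)")
  if (identical(pyro_dir, "Q")) {
    parts <- c(parts, "Gln->pyro-Glu (N-term Q)")
  } else if (identical(pyro_dir, "E")) {
    parts <- c(parts, "Glu->pyro-Glu (N-term E)")
  }
  paste(parts, collapse = "; ")
}

# tree-ancestry relation oracle, independent of the lineage-prefix code path
.tree_relation <- function(taxonomy, input_t, other_t) {
  if (input_t == other_t) return("identical")
  a <- .ancestor_chain(taxonomy, input_t)
  b <- .ancestor_chain(taxonomy, other_t)
  if (input_t %in% b) return("more_specific")
  if (other_t %in% a) return("less_specific")
  "different"
}

#' Generate a self-contained pipeline fixture
#'
#' Produces a peptide table (Mascot-dialect CSV), an offline peptide-to-LCA
#' table (TSV) derived from a toy taxonomy, and a manifest of expected
#' per-peptide results, all deterministic for a given spec. Each input
#' peptide is assigned a leaf set of the toy taxonomy (its offline LCA is
#' the tree LCA of that set), and selected permutations are planted onto
#' taxa chosen to realise each outcome class in rotation: no alternate
#' match, all-identical LCA, a different lineage, a more specific taxon and
#' a less specific (ancestral) taxon. The first row is a fixed worked
#' scenario: an unmodified peptide whose single-substitution permutation is
#' planted on a sibling genus, the classic two-species ambiguity. Expected
#' total permutation counts come from the closed-form count, and expected
#' categories/flags from tree ancestry, so the manifest is derivable without
#' running the screening pipeline.
#'
#' @param spec A `demisp_fixture_spec`.
#' @param dir Directory to write `peptides.csv`, `lca_table.tsv`,
#'   `manifest.csv` into (created if needed).
#' @return A list with `taxonomy`, `paths` (the three files) and `manifest`
#'   (data frame: sequence, modifications, expected_total_misps,
#'   expected_n_misps_with_lca, expected_category, expected_manual_check,
#'   expected_all_identical).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempdir()) {
  stopifnot(inherits(spec, "demisp_fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  taxonomy <- build_toy_taxonomy(spec$taxonomy_shape[1],
                                 spec$taxonomy_shape[2], spec$seed)
  nodes <- taxonomy$nodes
  leaves <- .leaves_under(taxonomy, taxonomy$root_id)
  internal <- setdiff(nodes$taxon_id, c(leaves, taxonomy$root_id))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  peptides <- list()
  # fixed worked scenario: sibling-genus ambiguity via one D->N substitution
  peptides[[1]] <- list(sequence = "TPEVDDEALEK", mods = "",
                        d = 0L, pyro = NULL, planted = "different")
  # fixed scenario for the manual-verification flag: fewer detected
  # deamidations than deamidatable residues, with two permutations planted
  # on distinct taxa
  peptides[[2]] <- list(sequence = "NNGKTEYGLFQINNK",
                        mods = "3 Deamidated (NQ)",
                        d = 3L, pyro = NULL, planted = "manual_flag")

  scenarios <- c("no_alternate", "all_identical", "different",
                 "more_specific", "less_specific")
  i <- 3L
  while (length(peptides) < spec$n_peptides) {
    len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    seq_i <- .random_peptide(len, spec$site_density)
    letters_i <- strsplit(seq_i, "")[[1]]
    n_nq <- sum(letters_i %in% c("N", "Q"))
    d <- min(sample(spec$deamidation_range, 1), n_nq)
    pyro <- NULL
    if (stats::runif(1) < spec$pyroglu_probability) {
      pyro <- sample(c("Q", "E"), 1)
      substr(seq_i, 1, 1) <- pyro
    }
    if (any(vapply(peptides, function(p) p$sequence == seq_i, NA))) next
    peptides[[i]] <- list(sequence = seq_i,
                          mods = .mods_string(d, pyro),
                          d = d, pyro = pyro,
                          planted = scenarios[(i - 2L) %% 5L + 1L])
    i <- i + 1L
  }

  # assign taxa: sequence -> leaf set (first assignment wins)
  assignment <- list()
  assign_once <- function(seq, leafset) {
    if (is.null(assignment[[seq]])) assignment[[seq]] <<- leafset
    invisible(NULL)
  }
  for (p in peptides) {
    profile <- parse_modifications(p$mods)
    pset <- enumerate_misps(p$sequence, profile)
    alts <- misp_sequences(pset, include_identity = FALSE)
    if (p$sequence == "TPEVDDEALEK") {
      # input on one genus leaf, permutation on a sibling genus leaf
      sibs <- nodes$taxon_id[!is.na(nodes$parent_id) &
                               nodes$parent_id == nodes$parent_id[
                                 match(leaves[1], nodes$taxon_id)]]
      assign_once(p$sequence, leaves[1])
      assign_once("TPEVDNEALEK", setdiff(sibs, leaves[1])[1])
      next
    }
    if (identical(p$planted, "manual_flag")) {
      root_children <- nodes$taxon_id[!is.na(nodes$parent_id) &
                                        nodes$parent_id == taxonomy$root_id]
      assign_once(p$sequence, min(.leaves_under(taxonomy, root_children[1])))
      if (length(alts) >= 2 && length(root_children) >= 3) {
        assign_once(alts[1], min(.leaves_under(taxonomy, root_children[2])))
        assign_once(alts[2], min(.leaves_under(taxonomy, root_children[3])))
      }
      next
    }
    input_leaf <- sample(leaves, 1)
    scenario <- p$planted
    if (length(alts) == 0 || scenario == "no_alternate") {
      assign_once(p$sequence, input_leaf)
      next
    }
    target_alt <- alts[1]
    if (scenario == "all_identical") {
      assign_once(p$sequence, input_leaf)
      assign_once(target_alt, input_leaf)
    } else if (scenario == "different") {
      root_children <- nodes$taxon_id[!is.na(nodes$parent_id) &
                                        nodes$parent_id == taxonomy$root_id]
      if (length(root_children) >= 2) {
        l1 <- min(.leaves_under(taxonomy, root_children[1]))
        l2 <- min(.leaves_under(taxonomy, root_children[2]))
        assign_once(p$sequence, l1)
        assign_once(target_alt, l2)
      } else {
        assign_once(p$sequence, input_leaf)
      }
    } else if (scenario == "more_specific") {
      anc <- if (length(internal) > 0) sample(internal, 1) else
        taxonomy$root_id
      assign_once(p$sequence, .leafset_with_lca(taxonomy, anc))
      assign_once(target_alt, min(.leaves_under(taxonomy, anc)))
    } else if (scenario == "less_specific") {
      chain <- .ancestor_chain(taxonomy, input_leaf)
      anc <- chain[max(1, length(chain) - 1)]
      assign_once(p$sequence, input_leaf)
      assign_once(target_alt, .leafset_with_lca(taxonomy, anc))
    }
  }

  lca_results <- lapply(names(assignment), function(s) {
    toy_lca_result(taxonomy, s, assignment[[s]])
  })
  lca_by_seq <- stats::setNames(
    vapply(lca_results, `[[`, 0L, "taxon_id"),
    vapply(lca_results, `[[`, "", "peptide")
  )

  # manifest from the closed-form count and tree-ancestry oracle
  manifest_rows <- lapply(peptides, function(p) {
    profile <- parse_modifications(p$mods)
    vp <- validate_record(peptide_record(p$sequence, p$mods), profile)
    sm <- substitutable_sites(vp$record$sequence, vp$profile)
    total <- expected_count(sm, vp$profile$deamidation_count)
    pset <- enumerate_misps(vp$record$sequence, vp$profile)
    alts <- misp_sequences(pset, include_identity = FALSE)
    matched <- alts[alts %in% names(lca_by_seq)]
    input_t <- lca_by_seq[[p$sequence]]
    rels <- vapply(matched, function(s) {
      .tree_relation(taxonomy, input_t, lca_by_seq[[s]])
    }, "")
    category <- if (length(matched) == 0) "no_alternate"
      else if (all(rels == "identical")) "all_identical"
      else if (any(rels == "less_specific")) "less_specific"
      else if (any(rels == "different")) "different"
      else "more_specific"
    letters_i <- strsplit(vp$record$sequence, "")[[1]]
    n_nq <- sum(letters_i %in% c("N", "Q")) -
      (vp$profile$pyroglu_from_q && letters_i[1] == "Q")
    d <- vp$profile$deamidation_count
    distinct_lcas <- length(unique(vapply(matched, function(s)
      lca_by_seq[[s]], 0L)))
    manual <- (d < n_nq) && (d != 0L) && (distinct_lcas >= 2L)
    all_ident <- all(c(input_t, vapply(matched, function(s)
      lca_by_seq[[s]], 0L)) == input_t)
    data.frame(
      sequence = p$sequence, modifications = p$mods,
      expected_total_misps = total,
      expected_n_misps_with_lca = length(matched),
      expected_category = category,
      expected_manual_check = manual,
      expected_all_identical = all_ident,
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, manifest_rows)

  paths <- c(
    peptides = file.path(dir, "peptides.csv"),
    lca_table = file.path(dir, "lca_table.tsv"),
    manifest = file.path(dir, "manifest.csv")
  )
  utils::write.csv(
    data.frame(Sequence = manifest$sequence,
               Modifications = manifest$modifications,
               stringsAsFactors = FALSE),
    paths[["peptides"]], row.names = FALSE
  )
  ord <- order(vapply(lca_results, `[[`, "", "peptide"), method = "radix")
  write_offline_table(lca_results[ord], paths[["lca_table"]])
  utils::write.csv(manifest, paths[["manifest"]], row.names = FALSE)

  list(taxonomy = taxonomy, paths = paths, manifest = manifest,
       assignment = assignment)
}
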