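#' Relation between two LCA lineages
#'
#' Compares the input peptide's LCA against the LCA of one of its sequence
#' permutations by lineage-prefix ancestry: `identical` for the same taxon;
#' `more_specific` when the input LCA is a strict ancestor of the other
#' (the permutation points to a finer taxon); `less_specific` for the
#' converse; `different` when neither lineage is a prefix of the other.
#' Ancestry uses the ordered taxon-id chains of the present ranks, so absent
#' (unranked) levels do not break the comparison.
#'
#' @param input_lca,other_lca `demisp_lca_result` objects with non-empty
#'   lineages.
#' @return One of `"identical"`, `"more_specific"`, `"less_specific"`,
#'   `"different"`.
#' @export
relation <- function(input_lca, other_lca) {
  a <- input_lca$lineage$taxon_id
  b <- other_lca$lineage$taxon_id
  if (length(a) == 0 || length(b) == 0) {
    stop("cannot compare an empty lineage", call. = FALSE)
  }
  if (input_lca$taxon_id == other_lca$taxon_id) return("identical")
  is_prefix <- function(x, y) {
    length(x) < length(y) && all(x == y[seq_along(x)])
  }
  if (is_prefix(a, b)) return("more_specific")
  if (is_prefix(b, a)) return("less_specific")
  "different"
}

#' Classify one input peptide from its permutation LCAs
#'
#' Category per input peptide, from the multiset of relations between the
#' input LCA and each permutation LCA (identity permutation excluded):
#' `no_alternate` when no permutation matched any protein; `all_identical`
#' when every permutation LCA equals the input's; otherwise
#' `less_specific` if at least one relation is less-specific (this overrides
#' the others, a less specific taxonomy being the more serious finding for
#' interpretation), else `different` if any relation is different, else
#' `more_specific`.
#'
#' @param input_lca `demisp_lca_result`, or `NULL` when the input peptide
#'   itself had no match.
#' @param misp_lcas List of `demisp_lca_result` for the non-identity
#'   permutations that matched.
#' @return A list with `category` and logical `warning_no_input_lca` (TRUE
#'   in the edge case where permutations matched but the input did not, for
#'   which the relations are undefined and `different` is reported).
#' @export
categorize_peptide <- function(input_lca, misp_lcas) {
  if (length(misp_lcas) == 0) {
    return(list(category = "no_alternate", warning_no_input_lca = FALSE))
  }
  if (is.null(input_lca)) {
    return(list(category = "different", warning_no_input_lca = TRUE))
  }
  rels <- vapply(misp_lcas, function(m) relation(input_lca, m), "")
  category <- if (all(rels == "identical")) "all_identical"
    else if (any(rels == "less_specific")) "less_specific"
    else if (any(rels == "different")) "different"
    else "more_specific"
  list(category = category, warning_no_input_lca = FALSE)
}

#' Are all LCAs identical?
#'
#' @param lcas List of `demisp_lca_result` (typically the input LCA together
#'   with all permutation LCAs).
#' @return TRUE iff the list is empty or every taxon_id equals the first.
#' @export
all_identical <- function(lcas) {
  if (length(lcas) == 0) return(TRUE)
  ids <- vapply(lcas, `[[`, 0L, "taxon_id")
  all(ids == ids[1])
}

#' Confusion matrix of input LCA versus permutation LCA
#'
#' @param pairs Data frame (or list of 2-element character vectors) of
#'   observed (input LCA name, permutation LCA name) pairs.
#' @return Integer matrix, input taxa as rows, permutation taxa as columns.
#' @export
confusion_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    inp <- as.character(pairs[[1]])
    oth <- as.character(pairs[[2]])
  } else {
    inp <- vapply(pairs, `[`, "", 1)
    oth <- vapply(pairs, `[`, "", 2)
  }
  if (length(inp) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  tab <- table(input = inp, misp = oth)
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Write a confusion matrix to CSV
#'
#' @param m Matrix from [confusion_matrix()].
#' @param path Output path; input taxa are rows, permutation taxa columns.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(m, path) {
  df <- as.data.frame(m)
  utils::write.csv(cbind(input_lca = rownames(m), df), path,
                   row.names = FALSE)
  invisible(path)
}
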