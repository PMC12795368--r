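#' Does a peptide need manual verification of its deamidation positions?
#'
#' The permutation engine sees only the peptide sequence, not the ion
#' coverage of the underlying spectral match, so it cannot know where the
#' detected deamidations sit. When the detected deamidation count is smaller
#' than the number of deamidatable residues the deamidations could occupy
#' several positions, some of which may not be supported by a given PSM, and
#' permutations built on unsupported positions may be impossible. A peptide
#' is flagged iff all three hold: (1) the deamidation count is less than the
#' total number of N and Q residues (excluding an N-terminal Q when the
#' Gln->pyro-Glu modification is set), (2) the deamidation count is not
#' zero, and (3) the matching non-identity permutations carry at least two
#' distinct LCAs (i.e. not all identical).
#'
#' @param record Validated `demisp_peptide_record`.
#' @param profile Its `demisp_mod_profile`.
#' @param misp_lcas List of `demisp_lca_result` for non-identity
#'   permutations (identity excluded).
#' @return Logical flag.
#' @export
needs_manual_check <- function(record, profile, misp_lcas) {
  letters_in <- strsplit(record$sequence, "")[[1]]
  nq <- sum(letters_in %in% c("N", "Q"))
  if (isTRUE(profile$pyroglu_from_q) && letters_in[1] == "Q") nq <- nq - 1L
  d <- profile$deamidation_count
  ids <- unique(vapply(misp_lcas, `[[`, 0L, "taxon_id"))
  (d < nq) && (d != 0L) && (length(ids) >= 2L)
}

#' Build the per-peptide summary record
#'
#' @param record Validated `demisp_peptide_record`.
#' @param profile Its `demisp_mod_profile`.
#' @param permutation_set `demisp_permutation_set` from [enumerate_misps()].
#' @param lca_map Result of [fetch_lcas()] covering the input sequence and
#'   every non-identity permutation.
#' @return A `demisp_summary_record`: input sequence and modifications,
#'   input LCA (or NULL), identity-inclusive `total_misps`, the non-identity
#'   permutations that matched (`misps_with_lca`), `all_lcas_identical` over
#'   input LCA plus permutation LCAs, `manual_check_required`, `category`
#'   and a `notes` field recording unresolved lookups.
#' @export
build_summary <- function(record, profile, permutation_set, lca_map) {
  seqs_all <- misp_sequences(permutation_set, include_identity = TRUE)
  seqs_alt <- misp_sequences(permutation_set, include_identity = FALSE)
  total_misps <- length(seqs_all)

  input_entry <- lca_map[[record$sequence]]
  if (is.null(input_entry)) {
    stop("lca_map does not cover the input sequence ", record$sequence,
         call. = FALSE)
  }
  input_lca <- if (identical(input_entry$status, "match")) input_entry$lca
    else NULL

  notes <- character(0)
  if (identical(input_entry$status, "unresolved")) {
    notes <- c(notes, paste0("input peptide unresolved: ",
                             input_entry$reason %||% "unknown"))
  }
  misps_with_lca <- list()
  for (s in seqs_alt) {
    entry <- lca_map[[s]]
    if (is.null(entry)) {
      stop("lca_map does not cover permutation ", s, call. = FALSE)
    }
    if (identical(entry$status, "match")) {
      misps_with_lca[[length(misps_with_lca) + 1]] <-
        list(sequence = s, lca = entry$lca)
    } else if (identical(entry$status, "unresolved")) {
      notes <- c(notes, paste0("permutation ", s, " unresolved: ",
                               entry$reason %||% "unknown"))
    }
  }
  misp_lcas <- lapply(misps_with_lca, `[[`, "lca")
  cat_res <- categorize_peptide(input_lca, misp_lcas)
  if (cat_res$warning_no_input_lca) {
    notes <- c(notes,
               "permutations matched but the input peptide did not; ",
               "category reported as different")
  }
  all_ident <- all_identical(c(
    if (!is.null(input_lca)) list(input_lca) else list(), misp_lcas
  ))
  structure(
    list(
      input_sequence = record$sequence,
      raw_modifications = record$raw_modifications,
      input_lca = input_lca,
      input_lca_status = input_entry$status,
      total_misps = total_misps,
      misps_with_lca = misps_with_lca,
      all_lcas_identical = all_ident,
      manual_check_required = needs_manual_check(record, profile, misp_lcas),
      category = cat_res$category,
      notes = notes
    ),
    class = "demisp_summary_record"
  )
}

#' Dataset-level statistics over the summaries
#'
#' Central statistics over the identity-inclusive permutation counts,
#' peptides with zero permutations included. Conventions (fixed so that
#' outputs are deterministic): the median of an even-length sample is the
#' lower middle value, the mode breaks ties toward the smallest value, and
#' the mean is truncated (not rounded) to one decimal.
#'
#' @param summaries List of `demisp_summary_record`.
#' @return A list with `n_peptides`, `n_with_misps`, `n_without_misps`,
#'   `total_misps_sum`, `median_misps`, `mode_misps`, `mean_misps`,
#'   `n_with_alternate_lca`.
#' @export
dataset_statistics <- function(summaries) {
  counts <- vapply(summaries, `[[`, 0L, "total_misps")
  n <- length(counts)
  if (n == 0) {
    return(list(n_peptides = 0L, n_with_misps = 0L, n_without_misps = 0L,
                total_misps_sum = 0L, median_misps = 0, mode_misps = 0L,
                mean_misps = 0, n_with_alternate_lca = 0L))
  }
  sorted <- sort(counts)
  med <- if (n %% 2 == 1) sorted[(n + 1) / 2] else sorted[n / 2]
  tab <- table(counts)
  vals <- as.integer(names(tab))
  mode_v <- min(vals[tab == max(tab)])
  # tiny epsilon so a mean that is exactly k/10 never truncates downward
  # through floating-point representation error
  mean_trunc <- floor(sum(counts) / n * 10 + 1e-9) / 10
  alt <- vapply(summaries, function(s) {
    !s$category %in% c("no_alternate", "all_identical")
  }, NA)
  list(
    n_peptides = n,
    n_with_misps = sum(counts > 0),
    n_without_misps = sum(counts == 0),
    total_misps_sum = sum(counts),
    median_misps = med,
    mode_misps = mode_v,
    mean_misps = mean_trunc,
    n_with_alternate_lca = sum(alt)
  )
}

.lca_label <- function(lca) {
  if (is.null(lca)) "" else lca$taxon_name
}

.summary_row <- function(s) {
  data.frame(
    input_sequence = s$input_sequence,
    modifications = s$raw_modifications,
    input_lca_id = if (is.null(s$input_lca)) NA_integer_ else
      s$input_lca$taxon_id,
    input_lca_name = if (is.null(s$input_lca)) "" else s$input_lca$taxon_name,
    input_lca_rank = if (is.null(s$input_lca)) "" else s$input_lca$taxon_rank,
    input_lca_status = s$input_lca_status,
    total_misps = s$total_misps,
    n_misps_with_lca = length(s$misps_with_lca),
    misps_with_lca = paste(
      vapply(s$misps_with_lca,
             function(m) paste0(m$sequence, "=", m$lca$taxon_name), ""),
      collapse = ";"
    ),
    all_lcas_identical = s$all_lcas_identical,
    manual_check_required = s$manual_check_required,
    category = s$category,
    notes = paste(s$notes, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Write the three output artifacts
#'
#' Writes `<stem>_results.csv` (one row per input peptide),
#' `<stem>_permutations.csv` (one row per generated permutation; the
#' identity permutation is flagged `is_identity=TRUE` with its LCA cell left
#' empty, since it duplicates the input LCA) and `<stem>_results.json`
#' (the same information nested, with a `schema_version` key). Output is
#' byte-stable across runs on identical input: row order follows the input,
#' permutations are in lexicographic order, and no floats are printed.
#'
#' @param summaries List of `demisp_summary_record`, input order.
#' @param permutation_records List of `demisp_permutation_set`, parallel to
#'   `summaries` (one per input row; the same sequence may occur with
#'   different modification profiles).
#' @param out_dir Output directory (must exist and be writable).
#' @param stem File-name stem.
#' @param lca_map Optional [fetch_lcas()] map, used to annotate permutation
#'   rows with match status.
#' @return Named character vector of the three written paths.
#' @export
write_outputs <- function(summaries, permutation_records, out_dir, stem,
                          lca_map = NULL) {
  if (!dir.exists(out_dir)) {
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  }
  paths <- c(
    results_csv = file.path(out_dir, paste0(stem, "_results.csv")),
    permutations_csv = file.path(out_dir, paste0(stem, "_permutations.csv")),
    results_json = file.path(out_dir, paste0(stem, "_results.json"))
  )

  results_df <- if (length(summaries) > 0) {
    do.call(rbind, lapply(summaries, .summary_row))
  } else {
    .summary_row(structure(
      list(input_sequence = "", raw_modifications = "", input_lca = NULL,
           input_lca_status = "", total_misps = 0L,
           misps_with_lca = list(), all_lcas_identical = TRUE,
           manual_check_required = FALSE, category = "", notes = character(0)),
      class = "demisp_summary_record"
    ))[0, ]
  }

  if (length(permutation_records) != length(summaries)) {
    stop("permutation_records must be parallel to summaries", call. = FALSE)
  }
  perm_rows <- list()
  for (si in seq_along(summaries)) {
    s <- summaries[[si]]
    pset <- permutation_records[[si]]
    matched <- stats::setNames(
      lapply(s$misps_with_lca, `[[`, "lca"),
      vapply(s$misps_with_lca, `[[`, "", "sequence")
    )
    for (seq in misp_sequences(pset, include_identity = TRUE)) {
      is_id <- identical(seq, s$input_sequence)
      lca <- if (is_id) NULL else matched[[seq]]
      status <- if (is_id) "identity" else if (!is.null(lca)) "match" else {
        entry <- if (!is.null(lca_map)) lca_map[[seq]] else NULL
        if (!is.null(entry)) entry$status else "no_match"
      }
      perm_rows[[length(perm_rows) + 1]] <- data.frame(
        input_sequence = s$input_sequence,
        modifications = s$raw_modifications,
        misp_sequence = seq,
        is_identity = is_id,
        lca_id = if (is.null(lca)) NA_integer_ else lca$taxon_id,
        lca_name = if (is.null(lca)) "" else lca$taxon_name,
        lca_rank = if (is.null(lca)) "" else lca$taxon_rank,
        status = status,
        stringsAsFactors = FALSE
      )
    }
  }
  perms_df <- if (length(perm_rows) > 0) do.call(rbind, perm_rows) else
    data.frame(input_sequence = character(0), modifications = character(0),
               misp_sequence = character(0), is_identity = logical(0),
               lca_id = integer(0), lca_name = character(0),
               lca_rank = character(0), status = character(0),
               stringsAsFactors = FALSE)

  json_obj <- list(
    schema_version = "1.0",
    peptides = lapply(seq_along(summaries), function(si) {
      s <- summaries[[si]]
      pset <- permutation_records[[si]]
      matched <- stats::setNames(
        lapply(s$misps_with_lca, `[[`, "lca"),
        vapply(s$misps_with_lca, `[[`, "", "sequence")
      )
      list(
        input_sequence = s$input_sequence,
        modifications = s$raw_modifications,
        input_lca = if (is.null(s$input_lca)) NULL else list(
          taxon_id = s$input_lca$taxon_id,
          taxon_name = s$input_lca$taxon_name,
          taxon_rank = s$input_lca$taxon_rank
        ),
        input_lca_status = s$input_lca_status,
        total_misps = s$total_misps,
        n_misps_with_lca = length(s$misps_with_lca),
        misps = lapply(misp_sequences(pset, include_identity = TRUE),
                       function(seq) {
          is_id <- identical(seq, s$input_sequence)
          lca <- if (is_id) NULL else matched[[seq]]
          list(
            sequence = seq,
            is_identity = is_id,
            lca = if (is.null(lca)) NULL else list(
              taxon_id = lca$taxon_id, taxon_name = lca$taxon_name,
              taxon_rank = lca$taxon_rank
            )
          )
        }),
        all_lcas_identical = s$all_lcas_identical,
        manual_check_required = s$manual_check_required,
        category = s$category,
        notes = as.list(s$notes)
      )
    })
  )

  tmp <- vapply(paths, function(p) paste0(p, ".tmp"), "")
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp), add = TRUE)
  utils::write.csv(results_df, tmp[["results_csv"]], row.names = FALSE,
                   na = "")
  utils::write.csv(perms_df, tmp[["permutations_csv"]], row.names = FALSE,
                   na = "")
  jsonlite::write_json(json_obj, tmp[["results_json"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  for (i in seq_along(paths)) file.rename(tmp[[i]], paths[[i]])
  ok <- TRUE
  paths
}
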