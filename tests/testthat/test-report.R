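tax_rep <- build_toy_taxonomy(4, 2)

lca_at <- function(peptide, taxon) toy_lca_result(tax_rep, peptide, taxon)

test_that("manual-check flag implements its three-conjunct truth table", {
  two_distinct <- list(lca_at("M1", 8L), lca_at("M2", 12L))
  one_only <- list(lca_at("M1", 8L))
  none <- list()

  cases <- list(
    # sequence, d, misp_lcas, expected: flag iff A (d < N/Q count) and
    # B (d != 0) and C (>= 2 distinct permutation LCAs)
    list("NNKGK", 1L, two_distinct, TRUE),    # A B C
    list("NNKGK", 1L, one_only, FALSE),       # A B !C
    list("NNKGK", 0L, two_distinct, FALSE),   # A !B C
    list("NNKGK", 0L, none, FALSE),           # A !B !C
    list("NNKGK", 2L, two_distinct, FALSE),   # !A B C
    list("NNKGK", 2L, one_only, FALSE),       # !A B !C
    list("GGKGK", 0L, two_distinct, FALSE),   # !A !B C
    list("GGKGK", 0L, none, FALSE)            # !A !B !C
  )
  for (cs in cases) {
    rec <- peptide_record(cs[[1]])
    got <- needs_manual_check(rec, make_profile(cs[[2]]), cs[[3]])
    expect_equal(got, cs[[4]],
                 info = sprintf("%s d=%d n_lcas=%d", cs[[1]], cs[[2]],
                                length(cs[[3]])))
  }

  # identical (non-distinct) permutation LCAs never trigger the flag
  same_twice <- list(lca_at("M1", 8L), lca_at("M2", 8L))
  expect_false(needs_manual_check(peptide_record("NNKGK"),
                                  make_profile(1L), same_twice))

  # the N-terminal Q is excluded from the deamidatable count under pyroGlu
  expect_true(needs_manual_check(peptide_record("QNKGK"),
                                 make_profile(1L), two_distinct))
  expect_false(needs_manual_check(peptide_record("QNKGK"),
                                  make_profile(1L, "Q"), two_distinct))
})

test_that("summaries wire counts, categories and the identity exclusion", {
  # the classic two-species case: input Bovinae-like, one permutation on a
  # sibling taxon
  rec <- peptide_record("TPEVDDEALEK")
  prof <- make_profile(0)
  pset <- enumerate_misps("TPEVDDEALEK", prof)
  lca_map <- list()
  lca_map[["TPEVDDEALEK"]] <- list(status = "match",
                                   lca = lca_at("TPEVDDEALEK", 8L))
  lca_map[["TPEVDNEALEK"]] <- list(status = "match",
                                   lca = lca_at("TPEVDNEALEK", 9L))
  for (s in misp_sequences(pset, include_identity = FALSE)) {
    if (is.null(lca_map[[s]])) lca_map[[s]] <- list(status = "no_match")
  }
  summ <- build_summary(rec, prof, pset, lca_map)
  expect_equal(summ$total_misps, 32L)
  expect_equal(length(summ$misps_with_lca), 1L)
  expect_equal(summ$category, "different")
  expect_false(summ$all_lcas_identical)
  # the identity sequence never appears among the matching permutations
  expect_false("TPEVDDEALEK" %in%
                 vapply(summ$misps_with_lca, `[[`, "", "sequence"))

  # empty permutation set
  rec2 <- peptide_record("GGGKK")
  pset2 <- enumerate_misps("GGGKK", make_profile(0))
  map2 <- list(GGGKK = list(status = "match", lca = lca_at("GGGKK", 8L)))
  summ2 <- build_summary(rec2, make_profile(0), pset2, map2)
  expect_equal(summ2$total_misps, 0L)
  expect_equal(summ2$category, "no_alternate")
  expect_false(summ2$manual_check_required)

  # single matching permutation with the input's own LCA
  rec3 <- peptide_record("WNLKGME")
  pset3 <- enumerate_misps("WNLKGME", make_profile(0))
  map3 <- list(
    WNLKGME = list(status = "match", lca = lca_at("WNLKGME", 8L)),
    WNLKGMQ = list(status = "match", lca = lca_at("WNLKGMQ", 8L))
  )
  summ3 <- build_summary(rec3, make_profile(0), pset3, map3)
  expect_true(summ3$all_lcas_identical)
  expect_equal(summ3$category, "all_identical")

  # unresolved lookups are noted, not silently dropped
  map4 <- list(
    WNLKGME = list(status = "match", lca = lca_at("WNLKGME", 8L)),
    WNLKGMQ = list(status = "unresolved", reason = "retries exhausted")
  )
  summ4 <- build_summary(rec3, make_profile(0), pset3, map4)
  expect_match(paste(summ4$notes, collapse = " "), "unresolved")
})

test_that("dataset statistics use the documented tie and rounding rules", {
  mk <- function(counts, cats = NULL) {
    lapply(seq_along(counts), function(i) {
      structure(list(total_misps = counts[i],
                     category = if (is.null(cats)) "no_alternate" else
                       cats[i]),
                class = "demisp_summary_record")
    })
  }
  s1 <- dataset_statistics(mk(c(0L, 2L, 4L)))
  expect_equal(s1$median_misps, 2L)
  expect_equal(s1$mode_misps, 0L)  # three-way tie broken to smallest

  s2 <- dataset_statistics(mk(c(2L, 2L, 4L, 0L)))
  expect_equal(s2$n_without_misps, 1L)
  expect_equal(s2$mode_misps, 2L)
  expect_equal(s2$median_misps, 2L)  # lower middle of 0,2,2,4

  # truncation, not rounding, of the mean (5/3 = 1.666... -> 1.6)
  s3 <- dataset_statistics(mk(c(1L, 2L, 2L)))
  expect_equal(s3$mean_misps, 1.6)

  s4 <- dataset_statistics(mk(c(0L, 4L, 8L),
                              c("no_alternate", "different",
                                "all_identical")))
  expect_equal(s4$n_with_alternate_lca, 1L)

  s0 <- dataset_statistics(list())
  expect_equal(s0$n_peptides, 0L)
  expect_equal(s0$total_misps_sum, 0L)
})

test_that("output files are consistent, conservative and byte-stable", {
  rec <- peptide_record("TPEVDDEALEK")
  prof <- make_profile(0)
  pset <- enumerate_misps("TPEVDDEALEK", prof)
  lca_map <- list()
  lca_map[["TPEVDDEALEK"]] <- list(status = "match",
                                   lca = lca_at("TPEVDDEALEK", 8L))
  lca_map[["TPEVDNEALEK"]] <- list(status = "match",
                                   lca = lca_at("TPEVDNEALEK", 9L))
  for (s in misp_sequences(pset, include_identity = FALSE)) {
    if (is.null(lca_map[[s]])) lca_map[[s]] <- list(status = "no_match")
  }
  summ <- build_summary(rec, prof, pset, lca_map)

  d1 <- tempfile(); dir.create(d1)
  p1 <- write_outputs(list(summ), list(pset), d1, "runA", lca_map = lca_map)
  expect_true(all(file.exists(p1)))

  results <- utils::read.csv(p1[["results_csv"]])
  perms <- utils::read.csv(p1[["permutations_csv"]])
  js <- jsonlite::fromJSON(p1[["results_json"]], simplifyVector = FALSE)

  # conservation: permutation rows account for every identity-inclusive count
  expect_equal(nrow(perms), sum(results$total_misps))
  expect_equal(sum(perms$is_identity == "TRUE" | perms$is_identity == TRUE),
               1L)
  # identity row carries no LCA even though the input matched
  id_row <- perms[perms$misp_sequence == "TPEVDDEALEK", ]
  expect_equal(id_row$lca_name, "")

  # JSON projects onto the CSVs
  expect_equal(js$schema_version, "1.0")
  jp <- js$peptides[[1]]
  expect_equal(jp$input_sequence, results$input_sequence[1])
  expect_equal(jp$total_misps, results$total_misps[1])
  expect_equal(length(jp$misps), nrow(perms))
  expect_equal(jp$category, results$category[1])

  # byte-stability across repeated writes
  d2 <- tempfile(); dir.create(d2)
  p2 <- write_outputs(list(summ), list(pset), d2, "runA", lca_map = lca_map)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", 1e6),
                     readBin(p2[[k]], "raw", 1e6))
  }

  # empty summaries give headers-only CSVs and an empty peptide list
  d3 <- tempfile(); dir.create(d3)
  p3 <- write_outputs(list(), list(), d3, "empty")
  expect_equal(length(readLines(p3[["results_csv"]])), 1L)
  expect_equal(length(readLines(p3[["permutations_csv"]])), 1L)
  js3 <- jsonlite::fromJSON(p3[["results_json"]], simplifyVector = FALSE)
  expect_length(js3$peptides, 0)

  expect_error(write_outputs(list(summ), list(pset),
                             file.path(tempdir(), "no-such-dir-xyz"), "x"),
               "does not exist")
})
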