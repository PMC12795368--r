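test_that("site maps list N/Q and D/E positions with N-terminal exclusions", {
  sm <- substitutable_sites("TPEVDDEALEK", make_profile(0))
  expect_length(sm$stage1_sites, 0)
  expect_equal(sm$stage2_sites, c(3L, 5L, 6L, 7L, 10L))
  expect_null(sm$pyroglu_site)

  smq <- substitutable_sites("QEVGGEALGR", make_profile(0, "Q"))
  expect_false(1L %in% smq$stage1_sites)
  expect_equal(smq$stage2_sites, c(2L, 6L))
  expect_equal(smq$pyroglu_site$direction, "QE")

  sme <- substitutable_sites("EEVGGEALGR", make_profile(0, "E"))
  expect_equal(sme$stage2_sites, c(2L, 6L))
  expect_equal(sme$pyroglu_site$direction, "EQ")

  sm0 <- substitutable_sites("GGGK", make_profile(0))
  expect_length(sm0$stage1_sites, 0)
  expect_length(sm0$stage2_sites, 0)
})

test_that("enumeration reproduces the worked peptide set sizes", {
  # beta-casein peptide with 3 detected deamidations: 7 N/Q sites, 6 D/E
  # sites, (C(7,0)+C(7,1)+C(7,2)+C(7,3)) * 2^6 = 4096
  ps <- enumerate_misps("FQSEEQQQTEDELQDKIHPFAQTQ", make_profile(3))
  expect_length(ps$permutations, 4096)
  expect_false(ps$truncated)

  # the classic two-species whey peptide: no N/Q, five D/E sites
  ps2 <- enumerate_misps("TPEVDDEALEK", make_profile(0))
  expect_length(ps2$permutations, 32)
  expect_true("TPEVDNEALEK" %in% misp_sequences(ps2))
  expect_true("TPEVDDEALEK" %in% misp_sequences(ps2))

  # no exchangeable residues at all: empty set, not a singleton identity
  expect_length(enumerate_misps("GGGK", make_profile(0))$permutations, 0)

  # N-terminal pyroglutamate doubles the set and swaps position 1
  ps3 <- enumerate_misps("QEVGGEALGR", make_profile(0, "Q"))
  expect_length(ps3$permutations, 8)
  expect_true(all(c("EEVGGEALGR", "QEVGGQALGR") %in% misp_sequences(ps3)))

  # unmatched deamidations without substitutable D/E still yield no set
  # when there are no N/Q either, but N/Q with d=0 yields no stage-1 moves
  ps4 <- enumerate_misps("ANGK", make_profile(0))
  expect_length(ps4$permutations, 0)
})

test_that("closed-form count matches its arithmetic examples", {
  sm <- list(stage1_sites = 1:7, stage2_sites = 1:6 + 10L,
             pyroglu_site = NULL)
  class(sm) <- "demisp_site_map"
  expect_equal(expected_count(sm, 3), 4096)

  sm2 <- list(stage1_sites = c(1L, 2L, 11L, 13L, 14L), stage2_sites = 6L,
              pyroglu_site = NULL)
  class(sm2) <- "demisp_site_map"
  expect_equal(expected_count(sm2, 3), 52)

  sm0 <- list(stage1_sites = integer(0), stage2_sites = integer(0),
              pyroglu_site = NULL)
  class(sm0) <- "demisp_site_map"
  expect_equal(expected_count(sm0, 5), 0)
})

test_that("engine agrees with the brute-force oracle and closed form", {
  set.seed(71)
  n_cases <- 0
  for (rep in 1:60) {
    len <- sample(3:10, 1)
    seq <- random_test_peptide(len)
    for (d in 0:3) {
      for (pyro in c("none", "Q", "E")) {
        first <- substr(seq, 1, 1)
        # a pyroGlu flag only survives validation on a matching first residue
        if (pyro == "Q" && first != "Q") next
        if (pyro == "E" && first != "E") next
        profile <- make_profile(d, pyro)
        ps <- enumerate_misps(seq, profile)
        got <- misp_sequences(ps)
        want <- brute_force_misps(seq, d, pyro)
        expect_equal(got, want,
                     info = sprintf("seq=%s d=%d pyro=%s", seq, d, pyro))
        sm <- substitutable_sites(seq, profile)
        expect_equal(length(got), expected_count(sm, d))
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gt(n_cases, 100)
})

test_that("permutations preserve length and touch only exchangeable sites", {
  set.seed(5)
  for (rep in 1:40) {
    seq <- random_test_peptide(sample(4:12, 1),
                               alphabet = strsplit(
                                 "ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    d <- sample(0:3, 1)
    ps <- enumerate_misps(seq, make_profile(d))
    in_letters <- strsplit(seq, "")[[1]]
    for (perm in ps$permutations) {
      out_letters <- strsplit(perm$sequence, "")[[1]]
      expect_length(out_letters, length(in_letters))
      changed <- which(out_letters != in_letters)
      expect_true(all(in_letters[changed] %in% c("N", "Q", "D", "E")))
    }
    # deterministic lexicographic order, no duplicate sequences
    seqs <- misp_sequences(ps)
    expect_equal(seqs, sort(unique(seqs), method = "radix"))
  }
})

test_that("masses follow the standard monoisotopic table", {
  expect_equal(base_monoisotopic_mass("G"), 57.02146 + 18.010565,
               tolerance = 1e-6)
  expect_error(base_monoisotopic_mass(""), "empty")
  expect_error(base_monoisotopic_mass("GXG"), "X")

  m <- mass_model()
  expect_equal(m$residue_masses[["D"]] - m$residue_masses[["N"]],
               m$deamidation_shift, tolerance = 1e-3)
  expect_equal(m$residue_masses[["E"]] - m$residue_masses[["Q"]],
               m$deamidation_shift, tolerance = 1e-3)
  # one reverse deamidation removes exactly one shift
  expect_equal(
    base_monoisotopic_mass("TPEVDNEALEK") + m$deamidation_shift,
    base_monoisotopic_mass("TPEVDDEALEK"),
    tolerance = 1e-3
  )
})

test_that("shift multiples equal the substitution balance", {
  ps <- enumerate_misps("TPEVDDEALEK", make_profile(0))
  identity <- Filter(function(p) p$sequence == "TPEVDDEALEK",
                     ps$permutations)[[1]]
  expect_equal(isobaric_shift_multiple("TPEVDDEALEK", identity), 0L)

  one_rev <- Filter(function(p) p$sequence == "TPEVDNEALEK",
                    ps$permutations)[[1]]
  expect_equal(isobaric_shift_multiple("TPEVDDEALEK", one_rev), -1L)

  ps3 <- enumerate_misps("FQSEEQQQTEDELQDKIHPFAQTQ", make_profile(3))
  full <- Filter(function(p)
    length(p$stage1_subset) == 3 && length(p$stage2_subset) == 0,
    ps3$permutations)[[1]]
  expect_equal(isobaric_shift_multiple("FQSEEQQQTEDELQDKIHPFAQTQ", full), 3L)
})

test_that("the cap truncates pathological inputs without erroring", {
  long <- paste(rep("DE", 30), collapse = "")  # 2^60 potential subsets
  expect_warning(
    ps <- enumerate_misps(long, make_profile(0), cap = 500L),
    "truncated"
  )
  expect_true(ps$truncated)
  expect_lte(length(ps$permutations), 500L)
  expect_error(
    enumerate_misps(long, make_profile(0), cap = 500L, strict = TRUE),
    "explosion"
  )
})

test_that("deamidation counts beyond the available sites are tolerated", {
  # only 2 N/Q sites but 5 detected deamidations: bound drops to 2
  ps <- enumerate_misps("ANGQK", make_profile(5))
  sm <- substitutable_sites("ANGQK", make_profile(5))
  expect_length(ps$permutations, expected_count(sm, 5))
  expect_equal(expected_count(sm, 5), (1 + 2 + 1) * 1)
})
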