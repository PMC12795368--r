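# Monoisotopic residue masses (Da), standard 20-letter alphabet.
# mass(D) - mass(N) = mass(E) - mass(Q) = 0.98402 Da: the deamidation shift.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MASS <- 18.010565
.DEAMIDATION_SHIFT <- 0.98402

#' The monoisotopic mass model used by the permutation engine
#'
#' @return A list with `residue_masses` (named numeric, 20 residues),
#'   `water_mass` and `deamidation_shift` (+0.984 Da at 3 d.p., stored at
#'   full precision 0.98402).
#' @export
mass_model <- function() {
  list(residue_masses = .RESIDUE_MASS, water_mass = .WATER_MASS,
       deamidation_shift = .DEAMIDATION_SHIFT)
}

#' Monoisotopic peptide mass
#'
#' @param sequence Peptide string over the 20-letter alphabet.
#' @param model A mass model from [mass_model()].
#' @return Neutral monoisotopic mass in Da (residue masses plus one water).
#' @export
base_monoisotopic_mass <- function(sequence, model = mass_model()) {
  if (!nzchar(sequence)) stop("empty sequence has no mass", call. = FALSE)
  letters_in <- strsplit(sequence, "")[[1]]
  m <- model$residue_masses[letters_in]
  if (anyNA(m)) {
    stop("unknown residue(s): ",
         paste(unique(letters_in[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  sum(m) + model$water_mass
}

#' Map the substitutable sites of a peptide
#'
#' Stage-1 sites are the N and Q positions eligible for deamidation
#' (N-terminal Q is excluded when Gln->pyro-Glu is set, because that residue
#' is handled by the pyroglutamate stage instead). Stage-2 sites are the D
#' and E positions eligible for reverse deamidation (N-terminal E excluded
#' when Glu->pyro-Glu is set). Positions are 1-based from the N-terminus.
#'
#' @param sequence Validated uppercase peptide.
#' @param profile A `demisp_mod_profile`.
#' @return A list of class `demisp_site_map` with `stage1_sites`,
#'   `stage2_sites` (integer vectors) and `pyroglu_site` (`NULL`, or a list
#'   with `position = 1` and `direction` `"QE"` or `"EQ"`).
#' @export
substitutable_sites <- function(sequence, profile) {
  letters_in <- strsplit(sequence, "")[[1]]
  stage1 <- which(letters_in %in% c("N", "Q"))
  stage2 <- which(letters_in %in% c("D", "E"))
  pyro <- NULL
  if (isTRUE(profile$pyroglu_from_q) && letters_in[1] == "Q") {
    stage1 <- setdiff(stage1, 1L)
    pyro <- list(position = 1L, direction = "QE")
  }
  if (isTRUE(profile$pyroglu_from_e) && letters_in[1] == "E") {
    stage2 <- setdiff(stage2, 1L)
    pyro <- list(position = 1L, direction = "EQ")
  }
  structure(
    list(stage1_sites = as.integer(stage1), stage2_sites = as.integer(stage2),
         pyroglu_site = pyro),
    class = "demisp_site_map"
  )
}

.has_substitutable_sites <- function(site_map, deamidation_count) {
  (deamidation_count >= 1L && length(site_map$stage1_sites) >= 1L) ||
    length(site_map$stage2_sites) >= 1L ||
    !is.null(site_map$pyroglu_site)
}

#' Closed-form count of the permutation set
#'
#' Analytic oracle for the three-stage enumeration: when any substitutable
#' site exists the set has size
#' \deqn{\left(\sum_{k=0}^{\min(d,s_1)} \binom{s_1}{k}\right) \cdot 2^{s_2}
#'   \cdot (2\ \mathrm{if\ pyroGlu\ else}\ 1)}
#' where \eqn{s_1}, \eqn{s_2} are the stage-1/stage-2 site counts and
#' \eqn{d} the detected deamidation count; otherwise 0. The stage rules make
#' duplicate sequences impossible, so this equals the deduplicated set size.
#'
#' @param site_map A `demisp_site_map`.
#' @param deamidation_count Non-negative integer.
#' @return Expected set size (double, to tolerate large counts).
#' @export
expected_count <- function(site_map, deamidation_count) {
  if (!.has_substitutable_sites(site_map, deamidation_count)) return(0)
  s1 <- length(site_map$stage1_sites)
  s2 <- length(site_map$stage2_sites)
  kmax <- min(deamidation_count, s1)
  stage1_total <- sum(choose(s1, 0:kmax))
  stage1_total * 2^s2 * (if (is.null(site_map$pyroglu_site)) 1 else 2)
}

# first m k-combinations of `positions` in lexicographic index order
.first_combinations <- function(positions, k, m) {
  n <- length(positions)
  out <- vector("list", m)
  idx <- seq_len(k)
  for (i in seq_len(m)) {
    out[[i]] <- as.integer(positions[idx])
    # lexicographic successor of the index combination
    j <- k
    while (j >= 1 && idx[j] == n - k + j) j <- j - 1
    if (j < 1) {
      out <- out[seq_len(i)]
      break
    }
    idx[j] <- idx[j] + 1
    if (j < k) idx[(j + 1):k] <- idx[j] + seq_len(k - j)
  }
  out
}

# subsets of `positions` with size <= kmax, smallest first then lexicographic,
# stopping once `limit` subsets have been produced (guards explosion: callers
# never need more than the permutation cap plus one)
.subsets_up_to <- function(positions, kmax, limit = Inf) {
  out <- list(integer(0))
  if (kmax >= 1 && length(positions) >= 1) {
    for (k in seq_len(min(kmax, length(positions)))) {
      remaining <- limit - length(out)
      if (remaining <= 0) break
      n_k <- choose(length(positions), k)
      combs <- if (length(positions) == 1L) {
        # combn(x, m) would misread a scalar x as seq_len(x)
        list(as.integer(positions))
      } else if (n_k <= remaining) {
        lapply(utils::combn(positions, k, simplify = FALSE), as.integer)
      } else {
        .first_combinations(positions, k, as.integer(remaining))
      }
      out <- c(out, combs)
    }
  }
  out
}

.SWAP <- c(N = "D", Q = "E", D = "N", E = "Q")

#' Enumerate the modification-induced sequence permutations of one peptide
#'
#' Three-stage procedure. Stage 1: every subset of the eligible N/Q sites of
#' size at most the detected deamidation count is substituted N->D, Q->E
#' (only such permutations share the observed mass, since only deamidated
#' N/Q are isobaric with D/E). Stage 2: on each stage-1 result, every subset
#' of the eligible D/E sites is reverse-substituted D->N, E->Q, with no
#' maximum (unmodified D/E are isobaric with deamidated N/Q). Stage 3: when
#' an N-terminal pyroglutamate modification was detected, each result
#' additionally spawns the variant with the first residue swapped Q<->E
#' (Q-NH3, E-H2O and pyroGlu are isobaric), keeping both forms. Duplicates
#' are removed (none can arise: the stages touch disjoint positions), and
#' the set is ordered lexicographically. The unchanged sequence is a member
#' whenever any substitutable site exists; a peptide with no D/E, no
#' deamidated N/Q and no pyroGlu yields the empty set.
#'
#' @param sequence Validated uppercase peptide.
#' @param profile A `demisp_mod_profile` (see [parse_modifications()]).
#' @param cap Maximum number of permutations to keep (default 1e6); when
#'   exceeded the set is truncated with a warning, or an error is raised in
#'   strict mode reporting the closed-form expected size.
#' @param strict Abort instead of truncating when `cap` is exceeded.
#' @return A list of class `demisp_permutation_set`: `input_sequence`,
#'   `permutations` (each with `sequence`, `stage1_subset`, `stage2_subset`,
#'   `pyroglu_applied`), `truncated`.
#' @export
enumerate_misps <- function(sequence, profile, cap = 1000000L,
                            strict = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.null(cap)) stopifnot(cap >= 1)
  site_map <- substitutable_sites(sequence, profile)
  d <- profile$deamidation_count
  empty_set <- structure(
    list(input_sequence = sequence, permutations = list(), truncated = FALSE),
    class = "demisp_permutation_set"
  )
  if (!.has_substitutable_sites(site_map, d)) return(empty_set)

  n_expected <- expected_count(site_map, d)
  if (!is.null(cap) && n_expected > cap && strict) {
    stop("permutation explosion for '", sequence, "': expected ",
         format(n_expected, scientific = FALSE), " permutations exceeds cap ",
         cap, call. = FALSE)
  }

  letters_in <- strsplit(sequence, "")[[1]]
  limit <- if (is.null(cap)) Inf else cap + 1
  stage1_subsets <- .subsets_up_to(site_map$stage1_sites, d, limit = limit)
  stage2_subsets <- .subsets_up_to(site_map$stage2_sites,
                                   length(site_map$stage2_sites),
                                   limit = limit)
  pyro <- site_map$pyroglu_site

  n_alloc <- length(stage1_subsets) * length(stage2_subsets) *
    (if (is.null(pyro)) 1L else 2L)
  if (!is.null(cap)) n_alloc <- min(n_alloc, cap)
  perms <- vector("list", n_alloc)
  idx <- 0L
  truncated <- FALSE
  for (S in stage1_subsets) {
    base1 <- letters_in
    base1[S] <- .SWAP[base1[S]]
    for (T in stage2_subsets) {
      base2 <- base1
      base2[T] <- .SWAP[base2[T]]
      variants <- list(list(seq = base2, pyro = FALSE))
      if (!is.null(pyro)) {
        swapped <- base2
        swapped[1] <- .SWAP[swapped[1]]
        variants <- c(variants, list(list(seq = swapped, pyro = TRUE)))
      }
      for (v in variants) {
        if (!is.null(cap) && idx >= cap) {
          truncated <- TRUE
          break
        }
        idx <- idx + 1L
        perms[[idx]] <- list(
          sequence = paste(v$seq, collapse = ""),
          stage1_subset = S, stage2_subset = T, pyroglu_applied = v$pyro
        )
      }
      if (truncated) break
    }
    if (truncated) break
  }
  perms <- perms[seq_len(idx)]
  if (truncated) {
    warning("permutation set for '", sequence, "' truncated at cap ", cap,
            " (expected ", format(n_expected, scientific = FALSE), ")",
            call. = FALSE)
  }

  seqs <- vapply(perms, `[[`, "", "sequence")
  keep <- !duplicated(seqs)
  perms <- perms[keep][order(seqs[keep], method = "radix")]
  structure(
    list(input_sequence = sequence, permutations = perms,
         truncated = truncated),
    class = "demisp_permutation_set"
  )
}

#' Sequences of a permutation set
#'
#' @param pset A `demisp_permutation_set`.
#' @param include_identity Keep the unchanged input sequence (default TRUE).
#' @return Character vector, lexicographic order.
#' @export
misp_sequences <- function(pset, include_identity = TRUE) {
  seqs <- vapply(pset$permutations, `[[`, "", "sequence")
  if (!include_identity) seqs <- seqs[seqs != pset$input_sequence]
  seqs
}

#' Integer deamidation-shift multiple between a permutation and its input
#'
#' Every permutation's neutral mass differs from the input's by an integer
#' multiple of the deamidation shift (0.98402 Da): +1 for each forward
#' substitution (N->D, Q->E), -1 for each reverse one, +/-1 for the
#' pyroglutamate swap. Given a valid deamidation assignment on the permuted
#' sequence, the observed (modified) masses coincide exactly.
#'
#' @param input_sequence The input peptide.
#' @param misp One element of `demisp_permutation_set$permutations`.
#' @param model Mass model.
#' @param tol Tolerance in Da for the integer check.
#' @return Integer multiple `m`.
#' @export
isobaric_shift_multiple <- function(input_sequence, misp,
                                    model = mass_model(), tol = 1e-3) {
  dm <- base_monoisotopic_mass(misp$sequence, model) -
    base_monoisotopic_mass(input_sequence, model)
  m <- round(dm / model$deamidation_shift)
  if (abs(dm - m * model$deamidation_shift) > tol) {
    stop("mass difference ", dm, " Da is not an integer multiple of the ",
         "deamidation shift within ", tol, " Da", call. = FALSE)
  }
  expected <- length(misp$stage1_subset) - length(misp$stage2_subset)
  if (isTRUE(misp$pyroglu_applied)) {
    first_in <- substr(input_sequence, 1, 1)
    expected <- expected + if (first_in == "Q") 1L else -1L
  }
  if (m != expected) {
    stop("internal inconsistency: mass multiple ", m,
         " does not match substitution provenance (", expected, ")",
         call. = FALSE)
  }
  as.integer(m)
}
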