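#' Detect the input table dialect from its header row
#'
#' Peptide tables exported by Mascot use a `Sequence`/`Modifications` column
#' pair in a comma-separated file, while MaxQuant's `evidence.txt` is
#' tab-separated and may use either that pair or `pep_seq`/`pep_var_mod`.
#' User-made minimal tables may use either pair with either separator.
#'
#' @param header_row Character vector of column names.
#' @param separator_hint Optional single character (`","` or `"\t"`) observed
#'   while sniffing the file; used to label the dialect.
#' @return A list of class `demisp_dialect` with elements `name`
#'   (`"mascot"`, `"maxquant"` or `"generic"`), `sequence_column`,
#'   `modification_column` and `separator`.
#' @export
detect_dialect <- function(header_row, separator_hint = NULL) {
  stopifnot(is.character(header_row), length(header_row) > 0)
  pairs <- list(
    c("Sequence", "Modifications"),
    c("pep_seq", "pep_var_mod")
  )
  hit <- NULL
  for (p in pairs) {
    if (p[1] %in% header_row) {
      hit <- p
      break
    }
  }
  if (is.null(hit)) {
    stop(
      "no recognized sequence column: expected one of 'Sequence' or ",
      "'pep_seq' (with modifications in 'Modifications' or 'pep_var_mod'); ",
      "header was: ", paste(header_row, collapse = ", "),
      call. = FALSE
    )
  }
  mod_col <- if (hit[2] %in% header_row) hit[2] else {
    # tolerate mixed pairs in user-made files
    alt <- setdiff(c("Modifications", "pep_var_mod"), hit[2])
    if (alt %in% header_row) alt else hit[2]
  }
  sep <- if (!is.null(separator_hint)) separator_hint else
    if (identical(hit[1], "pep_seq")) "\t" else ","
  name <- if (identical(hit[1], "Sequence") && identical(sep, ",")) "mascot"
    else if (identical(hit[1], "pep_seq") || identical(sep, "\t")) "maxquant"
    else "generic"
  structure(
    list(name = name, sequence_column = hit[1],
         modification_column = mod_col, separator = sep),
    class = "demisp_dialect"
  )
}

#' Read a peptide table into peptide records
#'
#' Accepts a CSV (Mascot export) or TSV (MaxQuant `evidence.txt`) with a
#' header row, or any minimal table carrying the recognized sequence and
#' modification columns. The separator is sniffed from the header line when
#' `dialect = "auto"`. Rows with an empty modification cell are treated as
#' unmodified. UTF-8 byte-order marks are tolerated.
#'
#' @param source Path to the input file.
#' @param dialect `"auto"` (default) or a `demisp_dialect` from
#'   [detect_dialect()].
#' @return A list of `demisp_peptide_record` objects, each with `sequence`,
#'   `raw_modifications` and zero-based `row_index` in file order.
#' @export
read_peptide_table <- function(source, dialect = "auto") {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty input file: ", source, call. = FALSE)
  lines[1] <- sub("^\uFEFF", "", lines[1])
  if (identical(dialect, "auto")) {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    header <- scan(text = lines[1], what = character(), sep = sep,
                   quiet = TRUE, quote = "\"")
    dialect <- detect_dialect(header, separator_hint = sep)
  }
  stopifnot(inherits(dialect, "demisp_dialect"))
  df <- utils::read.table(
    text = lines, header = TRUE, sep = dialect$separator,
    quote = "\"", comment.char = "", colClasses = "character",
    check.names = FALSE, stringsAsFactors = FALSE, fill = TRUE
  )
  if (!dialect$sequence_column %in% names(df)) {
    stop("missing required column '", dialect$sequence_column, "' in ",
         source, call. = FALSE)
  }
  seqs <- df[[dialect$sequence_column]]
  mods <- if (dialect$modification_column %in% names(df)) {
    df[[dialect$modification_column]]
  } else {
    rep("", nrow(df))
  }
  mods[is.na(mods)] <- ""
  lapply(seq_along(seqs), function(i) {
    peptide_record(seqs[[i]], mods[[i]], row_index = i - 1L)
  })
}

#' Construct a peptide record
#'
#' @param sequence Amino-acid sequence (any case; normalized later by
#'   [validate_record()]).
#' @param raw_modifications Free-text variable-modification cell (may be "").
#' @param row_index Zero-based source row index.
#' @return A `demisp_peptide_record`.
#' @export
peptide_record <- function(sequence, raw_modifications = "", row_index = 0L) {
  structure(
    list(sequence = as.character(sequence),
         raw_modifications = as.character(raw_modifications),
         row_index = as.integer(row_index)),
    class = "demisp_peptide_record"
  )
}

# Token sets: Mascot spells the modification "Deamidated (NQ)" and
# "Gln->pyro-Glu (N-term Q)"; MaxQuant uses "Deamidation (NQ)" and
# "Gln->pyro-Glu". All matched case-insensitively, with an optional leading
# multiplicity ("3 Deamidated (NQ)" means three events).
.DEAM_RE <- "^\\s*(\\d+)?\\s*x?\\s*deamidat(ed|ion)\\s*\\(\\s*nq\\s*\\)\\s*$"
.PYROQ_RE <- "gln\\s*(->|→)\\s*pyro-?glu"
.PYROE_RE <- "glu\\s*(->|→)\\s*pyro-?glu"

#' Parse a variable-modification cell into a normalized profile
#'
#' Splits the cell on `";"` and `","`, sums the multiplicities of deamidation
#' tokens, sets the pyroglutamate flags for Gln->pyro-Glu / Glu->pyro-Glu
#' tokens, and collects everything else (oxidation, carbamidomethyl, ...)
#' into `ignored_mods`. Total: any text yields a profile, never an error.
#'
#' @param text Modification cell contents; `""`, `NA` and `"(unmodified)"`
#'   all mean unmodified.
#' @param dialect Optional `demisp_dialect`; both vendors' spellings are
#'   always accepted, so the dialect only matters for provenance.
#' @return A `demisp_mod_profile` with `deamidation_count`, `pyroglu_from_q`,
#'   `pyroglu_from_e` and `ignored_mods`.
#' @export
parse_modifications <- function(text, dialect = NULL) {
  profile <- structure(
    list(deamidation_count = 0L, pyroglu_from_q = FALSE,
         pyroglu_from_e = FALSE, ignored_mods = character(0)),
    class = "demisp_mod_profile"
  )
  if (is.null(text) || length(text) == 0 || is.na(text)) return(profile)
  text <- trimws(as.character(text))
  if (!nzchar(text) || tolower(text) == "(unmodified)") return(profile)
  tokens <- trimws(unlist(strsplit(text, "[;,]")))
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    low <- tolower(tok)
    if (grepl(.DEAM_RE, low, perl = TRUE)) {
      n <- sub(.DEAM_RE, "\\1", low, perl = TRUE)
      profile$deamidation_count <- profile$deamidation_count +
        if (nzchar(n)) as.integer(n) else 1L
    } else if (grepl(.PYROQ_RE, low, perl = TRUE)) {
      profile$pyroglu_from_q <- TRUE
    } else if (grepl(.PYROE_RE, low, perl = TRUE)) {
      profile$pyroglu_from_e <- TRUE
    } else {
      profile$ignored_mods <- c(profile$ignored_mods, tok)
    }
  }
  if (profile$pyroglu_from_q && profile$pyroglu_from_e) {
    # both flags on one record is contradictory; keep the Q form, which is
    # the more common modification, and remember the dropped token
    profile$pyroglu_from_e <- FALSE
    profile$ignored_mods <- c(profile$ignored_mods,
                              "Glu->pyro-Glu (dropped: conflicting pyroGlu)")
  }
  profile
}

#' Validate and normalize one record/profile pair
#'
#' Uppercases the sequence, checks the 20-letter alphabet, and clears a
#' pyroglutamate flag that contradicts the first residue (with a warning)
#' so that batch runs complete instead of aborting.
#'
#' @param record A `demisp_peptide_record`.
#' @param profile A `demisp_mod_profile`.
#' @return A list with the normalized `record` and `profile`.
#' @export
validate_record <- function(record, profile) {
  stopifnot(inherits(record, "demisp_peptide_record"),
            inherits(profile, "demisp_mod_profile"))
  seq <- toupper(record$sequence)
  if (!nzchar(seq)) stop("empty peptide sequence at row_index ",
                         record$row_index, call. = FALSE)
  letters_in <- strsplit(seq, "")[[1]]
  bad <- unique(letters_in[!letters_in %in% AA_ALPHABET])
  if (length(bad) > 0) {
    stop("sequence '", record$sequence, "' (row_index ", record$row_index,
         ") contains non amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  record$sequence <- seq
  first <- substr(seq, 1, 1)
  if (profile$pyroglu_from_q && first != "Q") {
    warning("row_index ", record$row_index, ": Gln->pyro-Glu flagged but ",
            "sequence does not start with Q; flag cleared", call. = FALSE)
    profile$pyroglu_from_q <- FALSE
  }
  if (profile$pyroglu_from_e && first != "E") {
    warning("row_index ", record$row_index, ": Glu->pyro-Glu flagged but ",
            "sequence does not start with E; flag cleared", call. = FALSE)
    profile$pyroglu_from_e <- FALSE
  }
  list(record = record, profile = profile)
}

#' Write peptide records back to a generic CSV
#'
#' @param records List of `demisp_peptide_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  df <- data.frame(
    Sequence = vapply(records, `[[`, "", "sequence"),
    Modifications = vapply(records, `[[`, "", "raw_modifications"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
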