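#' Construct a lineage
#'
#' @param ranks,taxon_ids,names_ Parallel vectors, root-to-leaf; unranked
#'   levels are simply absent (gaps preserved).
#' @return A `demisp_lineage` data frame with columns `rank`, `taxon_id`,
#'   `name`.
#' @export
lineage <- function(ranks, taxon_ids, names_) {
  stopifnot(length(ranks) == length(taxon_ids),
            length(ranks) == length(names_))
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon_id within one lineage", call. = FALSE)
  }
  structure(
    data.frame(rank = as.character(ranks),
               taxon_id = as.integer(taxon_ids),
               name = as.character(names_),
               stringsAsFactors = FALSE),
    class = c("demisp_lineage", "data.frame")
  )
}

#' Construct an LCA result
#'
#' @param peptide Peptide sequence the LCA belongs to.
#' @param taxon_id,taxon_name,taxon_rank The LCA taxon; `taxon_id` must be
#'   the last entry of `lineage`.
#' @param lineage A `demisp_lineage`.
#' @return A `demisp_lca_result`.
#' @export
lca_result <- function(peptide, taxon_id, taxon_name, taxon_rank, lineage) {
  stopifnot(inherits(lineage, "demisp_lineage"), nrow(lineage) >= 1)
  if (lineage$taxon_id[nrow(lineage)] != taxon_id) {
    stop("taxon_id must be the last entry of its lineage", call. = FALSE)
  }
  structure(
    list(peptide = peptide, taxon_id = as.integer(taxon_id),
         taxon_name = taxon_name, taxon_rank = taxon_rank,
         lineage = lineage),
    class = "demisp_lca_result"
  )
}

#' Backend configuration for LCA resolution
#'
#' @param mode `"offline"` (lookup table) or `"unipept"` (live pept2lca).
#' @param api_url Unipept pept2lca endpoint.
#' @param offline_table Lookup from [load_offline_table()] (offline mode).
#' @param batch_size Peptides per request (default 90, below common public
#'   API request-size limits).
#' @param threads Worker lanes for live queries (default 8).
#' @param max_retries Retry attempts for transient failures (default 3).
#' @param backoff_base Seconds; attempt n waits `backoff_base * 2^(n-1)`.
#' @param equate_il Treat I and L as equal when querying (default FALSE:
#'   distinct treatment is the conservative choice for specificity).
#' @param timeout Per-request timeout in seconds.
#' @param min_length,max_length Peptides outside this length range are not
#'   sent to the live service and are reported unresolved with a reason.
#' @param transport,sleeper Internal injection points (testing): `transport`
#'   is called with (peptides, config) and must return the parsed JSON body;
#'   `sleeper` replaces `Sys.sleep`.
#' @return A `demisp_backend_config`.
#' @export
backend_config <- function(mode = c("offline", "unipept"),
                           api_url = "https://api.unipept.ugent.be/api/v2/pept2lca.json",
                           offline_table = NULL,
                           batch_size = 90L, threads = 8L,
                           max_retries = 3L, backoff_base = 0.5,
                           equate_il = FALSE, timeout = 30,
                           min_length = 5L, max_length = 50L,
                           transport = NULL, sleeper = Sys.sleep) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, threads >= 1, max_retries >= 0)
  if (mode == "offline" && is.null(offline_table)) {
    stop("offline mode requires an offline_table (see load_offline_table)",
         call. = FALSE)
  }
  structure(
    list(mode = mode, api_url = api_url, offline_table = offline_table,
         batch_size = as.integer(batch_size), threads = as.integer(threads),
         max_retries = as.integer(max_retries), backoff_base = backoff_base,
         equate_il = isTRUE(equate_il), timeout = timeout,
         min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         transport = transport, sleeper = sleeper),
    class = "demisp_backend_config"
  )
}

.parse_lineage_string <- function(s, line_no = NA) {
  if (is.na(s) || !nzchar(s)) {
    stop("empty lineage", if (!is.na(line_no)) paste0(" at line ", line_no),
         call. = FALSE)
  }
  triples <- strsplit(s, "|", fixed = TRUE)[[1]]
  parts <- lapply(triples, function(t) {
    # rank:taxon_id:name — names may themselves contain ':'; split twice
    p <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(p) < 3 || !grepl("^\\d+$", p[2])) {
      stop("malformed lineage triple '", t, "'",
           if (!is.na(line_no)) paste0(" at line ", line_no), call. = FALSE)
    }
    list(rank = p[1], taxon_id = as.integer(p[2]),
         name = paste(p[-(1:2)], collapse = ":"))
  })
  lineage(vapply(parts, `[[`, "", "rank"),
          vapply(parts, `[[`, 0L, "taxon_id"),
          vapply(parts, `[[`, "", "name"))
}

.format_lineage_string <- function(lin) {
  paste(sprintf("%s:%d:%s", lin$rank, lin$taxon_id, lin$name), collapse = "|")
}

#' Load an offline peptide-to-LCA lookup table
#'
#' The table is a TSV with header columns `peptide`, `taxon_id`,
#' `taxon_name`, `taxon_rank`, `lineage`, where `lineage` is a
#' pipe-separated list of `rank:taxon_id:name` triples, root to leaf. Later
#' duplicate peptide rows override earlier ones with a warning.
#'
#' @param path Path to the TSV.
#' @return A named list (environment-free) mapping peptide to
#'   `demisp_lca_result`, of class `demisp_offline_table`.
#' @export
load_offline_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("peptide", "taxon_id", "taxon_name", "taxon_rank", "lineage")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("offline table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lookup <- list()
  if (nrow(df) == 0) {
    warning("offline table ", path, " has no data rows", call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    lin <- .parse_lineage_string(df$lineage[i], line_no = i + 1L)
    res <- lca_result(df$peptide[i], as.integer(df$taxon_id[i]),
                      df$taxon_name[i], df$taxon_rank[i], lin)
    if (!is.null(lookup[[df$peptide[i]]])) {
      warning("duplicate offline-table row for peptide ", df$peptide[i],
              "; later row overrides", call. = FALSE)
    }
    lookup[[df$peptide[i]]] <- res
  }
  structure(lookup, class = "demisp_offline_table")
}

#' Write an offline lookup table
#'
#' @param results List of `demisp_lca_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_offline_table <- function(results, path) {
  df <- data.frame(
    peptide = vapply(results, `[[`, "", "peptide"),
    taxon_id = vapply(results, `[[`, 0L, "taxon_id"),
    taxon_name = vapply(results, `[[`, "", "taxon_name"),
    taxon_rank = vapply(results, `[[`, "", "taxon_rank"),
    lineage = vapply(results, function(r) .format_lineage_string(r$lineage),
                     ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# one entry of the fetch_lcas result map
.lca_entry <- function(status, lca = NULL, reason = NULL) {
  list(status = status, lca = lca, reason = reason)
}

# query one batch against the live service (or injected transport), with
# exponential-backoff retry on transient failures
.query_batch <- function(peptides, config) {
  transport <- config$transport
  if (is.null(transport)) transport <- .unipept_transport
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    out <- tryCatch(
      list(ok = TRUE, body = transport(peptides, config)),
      error = function(e) list(ok = FALSE, err = e)
    )
    if (out$ok) return(out)
    err <- out$err
    if (inherits(err, "demisp_config_error")) stop(err)
    if (attempt > config$max_retries) {
      return(list(ok = FALSE, err = err))
    }
    config$sleeper(config$backoff_base * 2^(attempt - 1))
  }
}

# live Unipept pept2lca transport over base-R url(): GET with repeated
# input[] parameters, extra=true and names=true for full lineages
.unipept_transport <- function(peptides, config) {
  q <- paste0(
    "input[]=", vapply(peptides, utils::URLencode, "", reserved = TRUE),
    collapse = "&"
  )
  url <- paste0(config$api_url, "?", q, "&extra=true&names=true",
                if (config$equate_il) "&equate_il=true" else "")
  old <- options(timeout = config$timeout)
  on.exit(options(old), add = TRUE)
  con <- url(url, open = "rb")
  on.exit(close(con), add = TRUE)
  jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = 50e6)),
                     simplifyVector = FALSE)
}

# convert one Unipept pept2lca JSON record (extra+names) to an lca_result
.unipept_record_to_lca <- function(rec) {
  entries <- list()
  for (rk in CANONICAL_RANKS) {
    id_field <- paste0(rk, "_id")
    name_field <- paste0(rk, "_name")
    if (!is.null(rec[[id_field]]) && !is.na(rec[[id_field]])) {
      entries[[length(entries) + 1]] <- list(
        rank = rk, taxon_id = as.integer(rec[[id_field]]),
        name = as.character(rec[[name_field]] %||% "")
      )
    }
  }
  lin <- if (length(entries) > 0) {
    lineage(vapply(entries, `[[`, "", "rank"),
            vapply(entries, `[[`, 0L, "taxon_id"),
            vapply(entries, `[[`, "", "name"))
  } else {
    lineage(rec$taxon_rank %||% "no rank", rec$taxon_id,
            rec$taxon_name %||% "")
  }
  # the LCA itself may sit below (or between) canonical ranks; append it
  if (lin$taxon_id[nrow(lin)] != rec$taxon_id) {
    lin <- lineage(c(lin$rank, rec$taxon_rank %||% "no rank"),
                   c(lin$taxon_id, rec$taxon_id),
                   c(lin$name, rec$taxon_name %||% ""))
  }
  lca_result(rec$peptide, rec$taxon_id, rec$taxon_name %||% "",
             rec$taxon_rank %||% "no rank", lin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve peptides to taxonomic LCAs
#'
#' Queries each distinct peptide once (duplicates are collapsed), in batches
#' of `batch_size`. In offline mode the lookup table is consulted directly;
#' in live mode batches are sent to the Unipept pept2lca endpoint with
#' retry/backoff on transient failures. The result map always contains every
#' input peptide: status `"match"` (with an LCA), `"no_match"` (the backend
#' knows no protein containing the peptide) or `"unresolved"` (retries
#' exhausted or peptide outside the length limits), which downstream reports
#' keep distinct from no-match.
#'
#' @param peptides Character vector of peptide sequences.
#' @param config A `demisp_backend_config`.
#' @return Named list: peptide -> list(status, lca, reason).
#' @export
fetch_lcas <- function(peptides, config) {
  stopifnot(length(peptides) >= 1)
  distinct <- unique(peptides)
  out <- stats::setNames(vector("list", length(distinct)), distinct)

  if (config$mode == "offline") {
    for (p in distinct) {
      hit <- config$offline_table[[p]]
      out[[p]] <- if (is.null(hit)) .lca_entry("no_match") else
        .lca_entry("match", lca = hit)
    }
    return(out)
  }

  lens <- nchar(distinct)
  skip <- lens < config$min_length | lens > config$max_length
  for (p in distinct[skip]) {
    out[[p]] <- .lca_entry(
      "unresolved",
      reason = sprintf("length %d outside [%d, %d]; not sent to service",
                       nchar(p), config$min_length, config$max_length)
    )
  }
  todo <- distinct[!skip]
  batches <- split(todo, ceiling(seq_along(todo) / config$batch_size))
  for (batch in batches) {
    res <- .query_batch(batch, config)
    if (!res$ok) {
      for (p in batch) {
        out[[p]] <- .lca_entry("unresolved",
                               reason = paste("retries exhausted:",
                                              conditionMessage(res$err)))
      }
      next
    }
    matched <- list()
    for (rec in res$body) {
      matched[[rec$peptide]] <- .unipept_record_to_lca(rec)
    }
    for (p in batch) {
      out[[p]] <- if (is.null(matched[[p]])) .lca_entry("no_match") else
        .lca_entry("match", lca = matched[[p]])
    }
  }
  out
}
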