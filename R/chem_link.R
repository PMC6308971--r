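# Hard linkage: CAS registry numbers -> ChEBI identifiers -> pathways.

#' Validate CAS registry numbers
#'
#' A CAS number is 2-7 digits, a hyphen, 2 digits, a hyphen and a single
#' check digit. The check digit is the weighted digit sum
#' \eqn{(\sum_i i \cdot d_i) \bmod 10}, digits numbered right to left
#' excluding the check digit itself. Water, "7732-18-5": 8*1 + 1*2 + 2*3 +
#' 3*4 + 7*5 + 7*6 = 105, and 105 mod 10 = 5.
#'
#' @param cas character vector of candidate CAS strings.
#' @return character vector with elements `"valid"`, `"bad_checksum"` or
#'   `"malformed"`.
#' @examples
#' validate_cas(c("7732-18-5", "50-00-0", "50-00-1", "ABC"))
#' @export
validate_cas <- function(cas) {
  vapply(as.character(cas), function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return("malformed")
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1L]])
    n <- length(digits)
    check <- digits[n]
    body <- rev(digits[-n]) # d_1 is the rightmost non-check digit
    if (sum(seq_along(body) * body) %% 10L == check) "valid" else "bad_checksum"
  }, character(1L), USE.NAMES = FALSE)
}

# Compute the check digit that makes `body` (digits, left to right) a valid
# CAS number. Used by the synthetic generator.
cas_check_digit <- function(body_digits) {
  body <- rev(body_digits)
  sum(seq_along(body) * body) %% 10L
}

#' Load a CAS to ChEBI identifier mapping table
#'
#' Reads a two-column tab-separated export (BridgeDb-style: one CAS/ChEBI
#' pair per row, duplicates allowed) into a multimap from normalized CAS
#' string to the set of ChEBI identifiers of the form `CHEBI:<digits>`.
#' Rows whose CAS fails syntactic validation are skipped with a warning;
#' CAS numbers with a bad checksum are kept (validation is diagnostic, not
#' a filter).
#'
#' @param path TSV file with header columns `cas` and `chebi`.
#' @return an object of class `cas_chebi_map`; use [chebi_for_cas()] to look
#'   keys up (absent keys return an empty set, never an error).
#' @export
load_cas_chebi_map <- function(path) {
  df <- read_tsv_checked(path, c("cas", "chebi"), "CAS-ChEBI mapping")
  df$cas <- normalize_cas(df$cas)
  df$chebi <- trimws(df$chebi)
  status <- validate_cas(df$cas)
  n_bad <- sum(status == "malformed")
  if (n_bad > 0L) {
    warning(sprintf("skipped %d row(s) with malformed CAS", n_bad), call. = FALSE)
    df <- df[status != "malformed", , drop = FALSE]
  }
  bad_chebi <- !grepl("^CHEBI:[0-9]+$", df$chebi)
  if (any(bad_chebi)) {
    warning(sprintf("skipped %d row(s) with malformed ChEBI identifier", sum(bad_chebi)),
            call. = FALSE)
    df <- df[!bad_chebi, , drop = FALSE]
  }
  map <- lapply(split(df$chebi, df$cas), function(v) sort(unique(v)))
  structure(list(cas_to_chebi = map, n_malformed_skipped = n_bad),
            class = "cas_chebi_map")
}

#' Look up the ChEBI identifiers mapped to a CAS number
#'
#' @param mapper a `cas_chebi_map`.
#' @param cas a single CAS string (normalized on the way in).
#' @return character vector of ChEBI IDs; empty for absent keys.
#' @export
chebi_for_cas <- function(mapper, cas) {
  stopifnot(inherits(mapper, "cas_chebi_map"))
  mapper$cas_to_chebi[[normalize_cas(cas)]] %||% character()
}

#' @export
print.cas_chebi_map <- function(x, ...) {
  cat(sprintf("CAS->ChEBI multimap: %d CAS keys, %d ChEBI IDs\n",
              length(x$cas_to_chebi),
              length(unique(unlist(x$cas_to_chebi, use.names = FALSE)))))
  invisible(x)
}

#' Map stressor chemicals to ChEBI and to pathways (hard linkage)
#'
#' For each unique normalized CAS among the stressor chemicals, looks up its
#' ChEBI identifiers in the mapping table and resolves those against the
#' pathway database's metabolite xrefs. Counts are over unique CAS numbers
#' and unique ChEBI IDs, not stressor multiplicity. An entirely unmapped
#' input is a legal outcome, not an error.
#'
#' @param mapper a `cas_chebi_map`.
#' @param chemicals the stressor-chemical data frame from
#'   [extract_chemicals()] (or any data frame with a `cas` column).
#' @param pathways a `pathway_db` from [load_pathway_table()] /
#'   [load_gpml_dir()], or NULL to skip pathway resolution.
#' @return an object of class `chemical_mapping`: `per_cas` (named list,
#'   CAS -> ChEBI set), `n_cas_in`, `n_cas_mapped`, `chebi_ids` (union),
#'   `chebi_in_pathways` (subset found among pathway metabolite xrefs),
#'   `pathways_hit` (pathway IDs containing any mapped ChEBI).
#' @export
map_chemicals <- function(mapper, chemicals, pathways = NULL) {
  stopifnot(inherits(mapper, "cas_chebi_map"))
  if (is.data.frame(chemicals)) cas <- chemicals$cas else cas <- chemicals
  cas <- unique(normalize_cas(cas))
  cas <- cas[nzchar(cas)]
  bad <- validate_cas(cas) == "bad_checksum"
  if (any(bad)) {
    warning(sprintf("%d CAS number(s) with bad checksum looked up anyway: %s",
                    sum(bad), paste(cas[bad], collapse = ", ")), call. = FALSE)
  }
  per_cas <- stats::setNames(lapply(cas, function(x) chebi_for_cas(mapper, x)), cas)
  mapped <- vapply(per_cas, function(v) length(v) > 0L, logical(1L))
  chebi_ids <- sort(unique(unlist(per_cas, use.names = FALSE)))
  if (!is.null(pathways)) {
    stopifnot(inherits(pathways, "pathway_db"))
    hit <- pathways$metabolite_xrefs[pathways$metabolite_xrefs$chebi %in% chebi_ids, , drop = FALSE]
    chebi_in_pathways <- sort(unique(hit$chebi))
    pathways_hit <- sort(unique(hit$pathway_id))
  } else {
    chebi_in_pathways <- character()
    pathways_hit <- character()
  }
  structure(list(
    per_cas = per_cas,
    n_cas_in = length(cas),
    n_cas_mapped = sum(mapped),
    chebi_ids = chebi_ids,
    chebi_in_pathways = chebi_in_pathways,
    pathways_hit = pathways_hit
  ), class = "chemical_mapping")
}

#' @export
print.chemical_mapping <- function(x, ...) {
  cat(sprintf("Chemical mapping: %d/%d CAS mapped to %d ChEBI IDs; %d ChEBI in %d pathways\n",
              x$n_cas_mapped, x$n_cas_in, length(x$chebi_ids),
              length(x$chebi_in_pathways), length(x$pathways_hit)))
  invisible(x)
}
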