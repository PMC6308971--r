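# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' Round half away from zero to integer percent
#'
#' Base R's `round()` rounds half to even; coverage percentages are displayed
#' with conventional half-up rounding so that 296/417 prints as 71.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' round_half_up(70.5) # 71
#' round_half_up(100 * 296 / 417) # 71
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Percent display: round_half_up(100 * num / den), NA when den == 0.
pct_of <- function(num, den) {
  if (is.na(den) || den == 0L) return(NA_integer_)
  round_half_up(100 * num / den)
}

# Strip markup from a text blob: remove XML/HTML tags, decode the common
# entities, collapse whitespace runs to single spaces, trim. This normalized
# text is the substrate for all downstream text matching.
strip_markup <- function(x) {
  if (length(x) == 0L || is.na(x)) return("")
  x <- gsub("<[^>]*>", " ", x)
  x <- gsub("&nbsp;", " ", x, fixed = TRUE)
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  x <- gsub("&quot;", "\"", x, fixed = TRUE)
  x <- gsub("&#39;|&apos;", "'", x)
  x <- gsub("&amp;", "&", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Word characters for tokenization are letters, digits and hyphen, so that
# forms like "IL-6" stay single tokens.
.token_regex <- "[A-Za-z0-9-]+"

# Tokenize normalized text; returns data.frame(token, start, end) with
# 0-based half-open character offsets.
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L),
             end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

# SHA-256 of a file, for provenance blocks.
file_sha256 <- function(path) {
  vapply(path, function(p) {
    if (file.exists(p)) digest::digest(file = p, algo = "sha256") else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

# JSON writer used by the CLI and reports: sorted keys where asked, LF line
# endings, no trailing whitespace, so golden outputs are diff-stable.
write_json_stable <- function(x, path = NULL) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                          digits = NA, pretty = 2L)
  txt <- gsub("\r\n", "\n", as.character(txt))
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(txt, "\n")), con)
  invisible(path)
}

# Read a TSV with a required header; errors name the missing columns.
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

run_provenance <- function(inputs = character()) {
  inputs <- inputs[!is.na(inputs) & nzchar(inputs)]
  list(
    tool = paste0("aoplink ", as.character(utils::packageVersion("aoplink"))),
    inputs = if (length(inputs)) {
      stats::setNames(as.list(file_sha256(inputs)), basename(inputs))
    } else {
      stats::setNames(list(), character())
    },
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
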