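# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from checked-in data files.

aop_ns <- "http://www.aopkb.org/aop-xml"

# Assemble a small AOP-Wiki-dialect dump from entity snippets.
write_dump <- function(..., ns = aop_ns, path = tempfile(fileext = ".xml")) {
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<data xmlns=\"%s\" created=\"test\">", ns),
    unlist(list(...)),
    "</data>"), path)
  path
}

ke_xml <- function(id, level = "molecular", description = "",
                   title = "a key event", annotations = character()) {
  c(sprintf("<key-event id=\"%s\">", id),
    sprintf("<title>%s</title>", title),
    if (!is.na(level)) sprintf("<biological-organization-level>%s</biological-organization-level>", level),
    if (!is.na(description)) sprintf("<description>%s</description>", description),
    annotations,
    "</key-event>")
}

ann_xml <- function(component, term_id, label = "term") {
  sprintf("<ontology-annotation component=\"%s\" term-id=\"%s\" term-label=\"%s\"/>",
          component, term_id, label)
}

ker_xml <- function(id, up, down, description = "", plaus = "", emp = "") {
  c(sprintf("<key-event-relationship id=\"%s\">", id),
    sprintf("<upstream-key-event>%s</upstream-key-event>", up),
    sprintf("<downstream-key-event>%s</downstream-key-event>", down),
    sprintf("<description>%s</description>", description),
    sprintf("<biological-plausibility>%s</biological-plausibility>", plaus),
    sprintf("<empirical-support>%s</empirical-support>", emp),
    "</key-event-relationship>")
}

stressor_xml <- function(id, name = "a stressor", chemicals = list()) {
  c(sprintf("<stressor id=\"%s\">", id),
    sprintf("<name>%s</name>", name),
    unlist(lapply(chemicals, function(ch)
      c(sprintf("<chemical cas=\"%s\">", ch$cas %||% ""),
        sprintf("<name>%s</name>", ch$name %||% ""),
        "</chemical>"))),
    "</stressor>")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Lexicon TSV from a data frame with the six canonical columns.
write_lexicon <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("hgnc_id", "approved_symbol", "approved_name",
              "previous_symbols", "synonyms", "ensembl_id")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r)
               paste(vapply(header, function(h) r[[h]] %||% "", character(1L)),
                     collapse = "\t"), character(1L)))
  writeLines(lines, path)
  path
}

lex_row <- function(hgnc_id, symbol, name = "", prev = "", syn = "", ensembl = "") {
  list(hgnc_id = hgnc_id, approved_symbol = symbol, approved_name = name,
       previous_symbols = prev, synonyms = syn, ensembl_id = ensembl)
}

write_cas_map <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("cas\tchebi",
               vapply(rows, function(r) paste(r[[1]], r[[2]], sep = "\t"),
                      character(1L))), path)
  path
}

write_pathway_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("pathway_id\ttitle\txref_namespace\txref_id",
               vapply(rows, function(r) paste(r, collapse = "\t"), character(1L))),
             path)
  path
}

# A default bundle cached per test run (generation is fast but used often).
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "bundle42")
      cache <<- generate_bundle(synthetic_config(seed = 42L), dir)
    }
    cache
  }
})
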