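# Independent SPARQL oracle: execute a query against a Turtle file in an
# in-process triple store (Python rdflib) and return (pathway, id) pairs
# with identifiers.org prefixes stripped. Used only as a cross-check of the
# package's table-lookup path.

sparql_pairs_via_rdflib <- function(ttl_path, query) {
  qf <- tempfile(fileext = ".rq")
  writeLines(query, qf)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph()",
    "g.parse(sys.argv[1], format='turtle')",
    "for row in g.query(open(sys.argv[2]).read()):",
    "    print(str(row[0]) + '\\t' + str(row[1]))"), py)
  out <- suppressWarnings(system2("python", c(py, ttl_path, qf),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("rdflib oracle failed: ", paste(out, collapse = "\n"))
  }
  if (!length(out)) {
    return(data.frame(pathway = character(), id = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(out, "\t", fixed = TRUE)
  strip <- function(x) sub("^http://identifiers\\.org/[a-z.]+/", "", x)
  data.frame(pathway = strip(vapply(parts, `[[`, character(1L), 1L)),
             id = strip(vapply(parts, `[[`, character(1L), 2L)),
             stringsAsFactors = FALSE)
}

python_rdflib_available <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", "import rdflib"),
                             stdout = FALSE, stderr = FALSE)) == 0L
}
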