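# Pathway-membership database: which pathways contain which genes and
# metabolites, and how pathways are annotated with ontology tags.

GENE_NAMESPACES <- c("HGNC_SYMBOL", "HGNC_ID", "ENSEMBL")
PATHWAY_TAG_SOURCES <- c("PW", "CL", "DO")
.GPML_NS_2013A <- "http://pathvisio.org/GPML/2013a"

new_pathway_db <- function(pathways, gene_xrefs, metabolite_xrefs, ontology_tags) {
  structure(list(
    pathways = pathways,
    gene_xrefs = unique(gene_xrefs),
    metabolite_xrefs = unique(metabolite_xrefs),
    ontology_tags = unique(ontology_tags)
  ), class = "pathway_db")
}

empty_pathway_db <- function() {
  new_pathway_db(
    data.frame(pathway_id = character(), title = character(), stringsAsFactors = FALSE),
    data.frame(pathway_id = character(), namespace = character(),
               xref_id = character(), stringsAsFactors = FALSE),
    data.frame(pathway_id = character(), chebi = character(), stringsAsFactors = FALSE),
    data.frame(pathway_id = character(), source = character(),
               term_id = character(), stringsAsFactors = FALSE)
  )
}

#' Load a pathway-membership database from a flat table
#'
#' A hermetic, local stand-in for a pathway database SPARQL endpoint: a
#' tab-separated table with columns `pathway_id`, `title`,
#' `xref_namespace`, `xref_id`. Gene xrefs use namespaces `HGNC_SYMBOL`,
#' `HGNC_ID`, `ENSEMBL`; metabolites use `CHEBI`; pathway-level ontology
#' tags use `PW` (Pathway Ontology), `CL` (Cell Ontology) or `DO` (Disease
#' Ontology) with the term in `xref_id`.
#'
#' @param path the TSV file.
#' @return an object of class `pathway_db`.
#' @export
load_pathway_table <- function(path) {
  df <- read_tsv_checked(path, c("pathway_id", "title", "xref_namespace", "xref_id"),
                         "pathway membership")
  if (nrow(df) == 0L) return(empty_pathway_db())
  # rows with an empty namespace register the pathway (title-only)
  known <- c(GENE_NAMESPACES, "CHEBI", PATHWAY_TAG_SOURCES, "")
  bad <- setdiff(unique(df$xref_namespace), known)
  if (length(bad)) {
    stop(sprintf("unknown xref_namespace value(s) in %s: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  first <- !duplicated(df$pathway_id)
  pathways <- data.frame(pathway_id = df$pathway_id[first],
                         title = df$title[first], stringsAsFactors = FALSE)
  g <- df[df$xref_namespace %in% GENE_NAMESPACES, , drop = FALSE]
  m <- df[df$xref_namespace == "CHEBI", , drop = FALSE]
  o <- df[df$xref_namespace %in% PATHWAY_TAG_SOURCES, , drop = FALSE]
  new_pathway_db(
    pathways,
    data.frame(pathway_id = g$pathway_id, namespace = g$xref_namespace,
               xref_id = g$xref_id, stringsAsFactors = FALSE),
    data.frame(pathway_id = m$pathway_id, chebi = m$xref_id, stringsAsFactors = FALSE),
    data.frame(pathway_id = o$pathway_id, source = o$xref_namespace,
               term_id = o$xref_id, stringsAsFactors = FALSE)
  )
}

#' Parse one GPML 2013a pathway file
#'
#' Extracts the membership view of a pathway diagram: `DataNode` elements of
#' type GeneProduct or Protein contribute gene xrefs (HGNC and Ensembl
#' databases normalized to the namespaces of [load_pathway_table()]; other
#' databases recorded as `OTHER`); Metabolite nodes with a ChEBI Xref
#' contribute metabolite xrefs; BioPAX `openControlledVocabulary` terms are
#' captured as pathway-level ontology tags. Only the GPML 2013a dialect is
#' accepted; other namespace versions are rejected with a clear message.
#'
#' @param file a GPML file; the pathway identifier is taken from the file
#'   name stem (WikiPathways convention, e.g. `WP3942.gpml`).
#' @return a list with `pathway_id`, `title`, `gene_xrefs` (namespace,
#'   xref_id), `metabolite_xrefs` (chebi), `ontology_tags` (source, term_id).
#' @export
parse_gpml <- function(file) {
  doc <- tryCatch(xml2::read_xml(file), error = function(e) {
    stop(sprintf("malformed GPML in %s: %s", file, conditionMessage(e)), call. = FALSE)
  })
  ns_uri <- xml2::xml_ns(doc)[["d1"]] %||% ""
  if (!identical(ns_uri, .GPML_NS_2013A)) {
    stop(sprintf("unsupported GPML namespace '%s' in %s; only GPML 2013a (%s) is supported",
                 ns_uri, file, .GPML_NS_2013A), call. = FALSE)
  }
  pathway_id <- sub("\\.[^.]*$", "", basename(file))
  title <- xml2::xml_attr(xml2::xml_root(doc), "Name") %|NA|% ""

  nodes <- xml2::xml_find_all(doc, ".//d1:DataNode")
  gene_xrefs <- list()
  met <- character()
  for (n in nodes) {
    type <- xml2::xml_attr(n, "Type") %|NA|% ""
    xref <- xml2::xml_find_first(n, "./d1:Xref")
    if (inherits(xref, "xml_missing")) {
      warning(sprintf("DataNode without Xref skipped in %s", basename(file)),
              call. = FALSE)
      next
    }
    db <- xml2::xml_attr(xref, "Database") %|NA|% ""
    id <- trimws(xml2::xml_attr(xref, "ID") %|NA|% "")
    if (!nzchar(id)) {
      warning(sprintf("DataNode with empty Xref ID skipped in %s", basename(file)),
              call. = FALSE)
      next
    }
    if (type %in% c("GeneProduct", "Protein")) {
      ns <- switch(db,
                   "HGNC" = "HGNC_SYMBOL",
                   "HGNC Accession number" = "HGNC_ID",
                   "Ensembl" = "ENSEMBL",
                   "OTHER")
      gene_xrefs[[length(gene_xrefs) + 1L]] <- c(ns, id)
    } else if (type == "Metabolite" && db == "ChEBI") {
      met <- c(met, if (grepl("^CHEBI:", id)) id else paste0("CHEBI:", id))
    }
  }
  gx <- if (length(gene_xrefs)) {
    data.frame(namespace = vapply(gene_xrefs, `[[`, character(1L), 1L),
               xref_id = vapply(gene_xrefs, `[[`, character(1L), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(namespace = character(), xref_id = character(), stringsAsFactors = FALSE)
  }

  ocv <- xml2::xml_find_all(doc, ".//bp:openControlledVocabulary/bp:ID",
                            ns = c(bp = "http://www.biopax.org/release/biopax-level3.owl#"))
  terms <- trimws(xml2::xml_text(ocv))
  src <- toupper(sub("^([A-Za-z]+)[:_].*$", "\\1", terms))
  src[src == "DOID"] <- "DO" # Disease Ontology terms are written DOID:<n>
  tags <- data.frame(source = src, term_id = terms, stringsAsFactors = FALSE)

  list(pathway_id = pathway_id, title = title,
       gene_xrefs = unique(gx),
       metabolite_xrefs = data.frame(chebi = unique(met), stringsAsFactors = FALSE),
       ontology_tags = unique(tags))
}

#' Load a pathway database from a directory of GPML files
#'
#' @param dir directory containing `*.gpml` files (one pathway each).
#' @return a `pathway_db` assembled from [parse_gpml()] records.
#' @export
load_gpml_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.gpml$", full.names = TRUE))
  recs <- lapply(files, parse_gpml)
  if (!length(recs)) return(empty_pathway_db())
  bind <- function(field) {
    do.call(rbind, lapply(recs, function(r) {
      d <- r[[field]]
      if (nrow(d) == 0L) return(NULL)
      cbind(data.frame(pathway_id = r$pathway_id, stringsAsFactors = FALSE), d)
    }))
  }
  gx <- bind("gene_xrefs")
  mx <- bind("metabolite_xrefs")
  ot <- bind("ontology_tags")
  db <- empty_pathway_db()
  new_pathway_db(
    data.frame(pathway_id = vapply(recs, `[[`, character(1L), "pathway_id"),
               title = vapply(recs, `[[`, character(1L), "title"),
               stringsAsFactors = FALSE),
    gx %||% db$gene_xrefs,
    mx %||% db$metabolite_xrefs,
    ot %||% db$ontology_tags
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("Pathway DB: %d pathways, %d gene xrefs, %d metabolite xrefs, %d ontology tags\n",
              nrow(x$pathways), nrow(x$gene_xrefs), nrow(x$metabolite_xrefs),
              nrow(x$ontology_tags)))
  invisible(x)
}

#' Pathway coverage of a gene set
#'
#' A gene is covered if any of its identifiers -- HGNC ID, approved symbol,
#' or Ensembl ID, bridged through the lexicon -- appears among any pathway's
#' gene xrefs in the matching namespace.
#'
#' @param gene_ids character vector of lexicon gene IDs (HGNC-style).
#' @param db a `pathway_db`.
#' @param lexicon the `gene_lexicon` supplying each gene's approved symbol
#'   and Ensembl ID for cross-namespace lookup.
#' @return list with `covered` (sorted subset of `gene_ids`),
#'   `per_gene_pathways` (named list gene_id -> sorted pathway IDs),
#'   `fraction` (|covered| / |gene_ids|; NA when `gene_ids` is empty),
#'   and `namespaces_hit` (named list gene_id -> namespaces that produced
#'   hits).
#' @export
genes_pathway_coverage <- function(gene_ids, db, lexicon) {
  stopifnot(inherits(db, "pathway_db"), inherits(lexicon, "gene_lexicon"))
  gene_ids <- unique(gene_ids)
  if (length(gene_ids) == 0L) {
    return(list(covered = character(), per_gene_pathways = stats::setNames(list(), character()),
                fraction = NA_real_, namespaces_hit = stats::setNames(list(), character())))
  }
  ent <- lexicon$entries
  gx <- db$gene_xrefs
  per_gene <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  ns_hit <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  for (g in gene_ids) {
    row <- match(g, ent$gene_id)
    ids <- c(HGNC_ID = g,
             HGNC_SYMBOL = if (!is.na(row)) ent$approved_symbol[[row]] else "",
             ENSEMBL = if (!is.na(row)) ent$ensembl_id[[row]] else "")
    hits <- gx[paste(gx$namespace, gx$xref_id) %in%
                 paste(names(ids), ids)[nzchar(ids)], , drop = FALSE]
    per_gene[[g]] <- sort(unique(hits$pathway_id))
    ns_hit[[g]] <- sort(unique(hits$namespace))
  }
  covered <- sort(gene_ids[lengths(per_gene[gene_ids]) > 0L])
  list(covered = covered,
       per_gene_pathways = per_gene,
       fraction = length(covered) / length(gene_ids),
       namespaces_hit = ns_hit)
}

#' Ontology-tag usage across pathways
#'
#' @param db a `pathway_db`.
#' @return list with `pathways_total` and, per ontology source PW/CL/DO, the
#'   number of pathways carrying at least one tag from it (each pathway
#'   counted at most once per source).
#' @export
pathway_ontology_usage <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  tag <- db$ontology_tags
  count_src <- function(s) length(unique(tag$pathway_id[tag$source == s]))
  list(pathways_total = nrow(db$pathways),
       with_pw = count_src("PW"),
       with_cl = count_src("CL"),
       with_do = count_src("DO"))
}

.WP_PREFIXES <- paste(
  "PREFIX wp: <http://vocabularies.wikipathways.org/wp#>",
  "PREFIX dcterms: <http://purl.org/dc/terms/>",
  sep = "\n")

gene_id_iri <- function(id) {
  if (grepl("^HGNC:", id)) {
    paste0("<http://identifiers.org/hgnc/", id, ">")
  } else if (grepl("^ENSG", id)) {
    paste0("<http://identifiers.org/ensembl/", id, ">")
  } else {
    paste0("<http://identifiers.org/hgnc.symbol/", id, ">")
  }
}

metabolite_iri <- function(id) {
  paste0("<http://identifiers.org/chebi/", id, ">")
}

#' Build a SPARQL pathway-membership query
#'
#' Produces a SPARQL SELECT over the WikiPathways RDF vocabulary returning
#' `(pathway, id)` pairs for the given identifiers. Identifiers are sorted
#' into the VALUES clause so the output is reproducible byte-for-byte. Gene
#' identifiers are dispatched on their shape: `HGNC:<n>` to the HGNC
#' accession predicate, `ENSG...` to Ensembl, anything else to the HGNC
#' symbol predicate; metabolites use the ChEBI predicate.
#'
#' @param ids non-empty character vector of identifiers.
#' @param id_kind `"gene"` or `"metabolite"`.
#' @return a single SPARQL query string.
#' @export
build_sparql_membership_query <- function(ids, id_kind = c("gene", "metabolite")) {
  id_kind <- match.arg(id_kind)
  ids <- sort(unique(ids))
  if (length(ids) == 0L) stop("'ids' must be non-empty", call. = FALSE)
  iris <- if (id_kind == "gene") vapply(ids, gene_id_iri, character(1L))
          else vapply(ids, metabolite_iri, character(1L))
  values <- paste0("  VALUES ?idIri { ", paste(iris, collapse = " "), " }")
  pred_block <- if (id_kind == "gene") {
    paste("  { ?node wp:bdbHgncSymbol ?idIri }",
          "  UNION { ?node wp:bdbHgnc ?idIri }",
          "  UNION { ?node wp:bdbEnsembl ?idIri }", sep = "\n")
  } else {
    "  ?node wp:bdbChEBI ?idIri ."
  }
  paste(.WP_PREFIXES,
        "SELECT DISTINCT ?pathway ?idIri WHERE {",
        values,
        "  ?node dcterms:isPartOf ?pathway .",
        "  ?pathway a wp:Pathway .",
        pred_block,
        "}",
        sep = "\n")
}

#' Execute a SPARQL query against a remote endpoint
#'
#' Optional remote mode for verifying local results against a live pathway
#' database endpoint. Performs an HTTP GET with `Accept:
#' text/tab-separated-values`. Never used by the package's own pipeline or
#' tests, which run on local tables and fixtures.
#'
#' @param query a SPARQL query string.
#' @param endpoint endpoint URL.
#' @return data frame parsed from the TSV response.
#' @export
query_sparql_endpoint <- function(query, endpoint) {
  u <- paste0(endpoint, "?query=", utils::URLencode(query, reserved = TRUE))
  con <- url(u, headers = c(Accept = "text/tab-separated-values"))
  on.exit(close(con))
  utils::read.delim(con, stringsAsFactors = FALSE)
}
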