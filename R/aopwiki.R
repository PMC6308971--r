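# Biological-organization levels recognised in AOP-Wiki key events.
AOP_LEVELS <- c("molecular", "cellular", "tissue", "organ",
                "individual", "population", "unspecified")

# The four levels the linkage analysis operates on: KEs above the organ
# level (individual, population) rarely describe molecular biology.
IN_SCOPE_LEVELS <- c("molecular", "cellular", "tissue", "organ")

# Ontology-source codes seen in AOP-Wiki annotations; anything else is OTHER.
ONTOLOGY_SOURCES <- c("GO", "CHEBI", "PR", "MI", "CL", "UBERON", "FMA",
                      "VT", "HP", "MP", "WIKI", "MESH")

ANNOTATION_COMPONENTS <- c("biological_process", "biological_object",
                           "cell_term", "organ_term")

ontology_source_from_id <- function(term_id) {
  prefix <- toupper(sub("^([A-Za-z]+)[:_].*$", "\\1", term_id))
  prefix[prefix == "PRO"] <- "PR"
  out <- ifelse(prefix %in% ONTOLOGY_SOURCES, prefix, "OTHER")
  out[!grepl("^[A-Za-z]+[:_]", term_id)] <- "OTHER"
  out
}

normalize_level <- function(x) {
  if (is.null(x)) x <- ""
  x <- tolower(trimws(x))
  out <- character(length(x))
  known <- x %in% AOP_LEVELS
  out[known] <- x[known]
  out[x == ""] <- "unspecified"
  unknown <- !known & x != ""
  if (any(unknown)) {
    warning(sprintf("unknown biological-organization level(s) mapped to 'unspecified': %s",
                    paste(unique(x[unknown]), collapse = ", ")), call. = FALSE)
    out[unknown] <- "unspecified"
  }
  out
}

normalize_cas <- function(x) {
  if (is.null(x)) return("")
  trimws(x)
}

#' Parse an AOP-Wiki XML dump
#'
#' Reads an AOP-Wiki quarterly XML dump (plain or gzip-compressed, sniffed by
#' magic bytes) into a typed in-memory dataset of key events (KEs), key event
#' relationships (KERs) and chemical stressors, together with the ontology
#' annotations attached to each KE. Markup inside description fields is
#' stripped to plain text with single-space normalization; element order is
#' preserved. KER endpoints that do not resolve to a KE in the dump are
#' recorded in `unresolved_refs`, never silently dropped.
#'
#' @param path path to the XML dump. The document must declare a single
#'   AOP-Wiki namespace on its root element; the namespace URI is read from
#'   the document rather than hard-coded, so quarterly dumps of different
#'   dates parse alike.
#' @return an object of class `aopwiki_dataset`: a list with data frames
#'   `key_events` (ke_id, title, level, description), `annotations`
#'   (ke_id, component, source, term_id, term_label), `kers` (ker_id,
#'   upstream_ke, downstream_ke, description, biological_plausibility,
#'   empirical_support), `stressors` (stressor_id, stressor_name,
#'   chemical_name, cas; one row per stressor-chemical pair), a data frame
#'   `unresolved_refs`, and `source_version` (the dump's `created` label when
#'   present).
#' @seealso [filter_key_events()], [extract_chemicals()],
#'   [ontology_usage_summary()]
#' @export
parse_aopwiki_xml <- function(path) {
  if (!file.exists(path)) stop("AOP-Wiki XML file not found: ", path, call. = FALSE)
  doc <- tryCatch(read_xml_any(path), error = function(e) {
    stop(sprintf("malformed XML in %s: %s", path, conditionMessage(e)), call. = FALSE)
  })
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(doc)[["d1"]] %||% ""
  if (!grepl("aop", tolower(ns_uri), fixed = TRUE)) {
    stop(sprintf("unknown XML namespace '%s'; expected an AOP-Wiki dump namespace",
                 ns_uri), call. = FALSE)
  }
  source_version <- xml2::xml_attr(root, "created")
  if (is.na(source_version)) source_version <- ""

  ke_nodes <- xml2::xml_find_all(doc, ".//d1:key-event")
  ke_id <- xml2::xml_attr(ke_nodes, "id")
  if (any(is.na(ke_id) | !nzchar(ke_id))) {
    stop("key-event entity without mandatory 'id' attribute", call. = FALSE)
  }
  if (anyDuplicated(ke_id)) {
    stop(sprintf("duplicate key-event identifier(s): %s",
                 paste(unique(ke_id[duplicated(ke_id)]), collapse = ", ")),
         call. = FALSE)
  }
  child_text <- function(nodes, name) {
    vapply(nodes, function(n) {
      ch <- xml2::xml_find_first(n, paste0("./d1:", name))
      if (inherits(ch, "xml_missing")) "" else xml2::xml_text(ch)
    }, character(1L))
  }
  key_events <- data.frame(
    ke_id = ke_id,
    title = strip_markup_v(child_text(ke_nodes, "title")),
    level = normalize_level(child_text(ke_nodes, "biological-organization-level")),
    description = strip_markup_v(child_text(ke_nodes, "description")),
    stringsAsFactors = FALSE
  )

  ann <- do.call(rbind, lapply(seq_along(ke_nodes), function(i) {
    a <- xml2::xml_find_all(ke_nodes[[i]], "./d1:ontology-annotation")
    if (!length(a)) return(NULL)
    data.frame(ke_id = ke_id[[i]],
               component = tolower(xml2::xml_attr(a, "component")),
               term_id = xml2::xml_attr(a, "term-id") %|NA|% "",
               term_label = xml2::xml_attr(a, "term-label") %|NA|% "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann)) {
    ann <- data.frame(ke_id = character(), component = character(),
                      term_id = character(), term_label = character(),
                      stringsAsFactors = FALSE)
  }
  bad_comp <- !(ann$component %in% ANNOTATION_COMPONENTS)
  if (any(bad_comp)) {
    warning(sprintf("dropping %d ontology annotation(s) with unknown component: %s",
                    sum(bad_comp), paste(unique(ann$component[bad_comp]), collapse = ", ")),
            call. = FALSE)
    ann <- ann[!bad_comp, , drop = FALSE]
  }
  ann$source <- ontology_source_from_id(ann$term_id)
  ann <- ann[, c("ke_id", "component", "source", "term_id", "term_label")]
  rownames(ann) <- NULL

  ker_nodes <- xml2::xml_find_all(doc, ".//d1:key-event-relationship")
  ker_id <- xml2::xml_attr(ker_nodes, "id")
  if (length(ker_nodes) && any(is.na(ker_id) | !nzchar(ker_id))) {
    stop("key-event-relationship entity without mandatory 'id' attribute",
         call. = FALSE)
  }
  kers <- data.frame(
    ker_id = ker_id %||% character(),
    upstream_ke = child_text(ker_nodes, "upstream-key-event"),
    downstream_ke = child_text(ker_nodes, "downstream-key-event"),
    description = strip_markup_v(child_text(ker_nodes, "description")),
    biological_plausibility = strip_markup_v(child_text(ker_nodes, "biological-plausibility")),
    empirical_support = strip_markup_v(child_text(ker_nodes, "empirical-support")),
    stringsAsFactors = FALSE
  )

  unresolved <- data.frame(ker_id = character(), role = character(),
                           ke_id = character(), stringsAsFactors = FALSE)
  if (nrow(kers)) {
    unresolved <- rbind(
      data.frame(ker_id = kers$ker_id, role = "upstream", ke_id = kers$upstream_ke,
                 stringsAsFactors = FALSE)[!(kers$upstream_ke %in% ke_id), , drop = FALSE],
      data.frame(ker_id = kers$ker_id, role = "downstream", ke_id = kers$downstream_ke,
                 stringsAsFactors = FALSE)[!(kers$downstream_ke %in% ke_id), , drop = FALSE]
    )
  }
  rownames(unresolved) <- NULL

  st_nodes <- xml2::xml_find_all(doc, ".//d1:stressor")
  st_id <- xml2::xml_attr(st_nodes, "id")
  if (length(st_nodes) && any(is.na(st_id) | !nzchar(st_id))) {
    stop("stressor entity without mandatory 'id' attribute", call. = FALSE)
  }
  stressors <- do.call(rbind, lapply(seq_along(st_nodes), function(i) {
    n <- st_nodes[[i]]
    sname <- strip_markup(xml2::xml_text(xml2::xml_find_first(n, "./d1:name")))
    chem <- xml2::xml_find_all(n, "./d1:chemical")
    if (!length(chem)) {
      return(data.frame(stressor_id = st_id[[i]], stressor_name = sname,
                        chemical_name = "", cas = "", stringsAsFactors = FALSE))
    }
    data.frame(
      stressor_id = st_id[[i]], stressor_name = sname,
      chemical_name = vapply(chem, function(c) {
        nm <- xml2::xml_find_first(c, "./d1:name")
        if (inherits(nm, "xml_missing")) "" else strip_markup(xml2::xml_text(nm))
      }, character(1L)),
      cas = normalize_cas(xml2::xml_attr(chem, "cas") %|NA|% ""),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(stressors)) {
    stressors <- data.frame(stressor_id = character(), stressor_name = character(),
                            chemical_name = character(), cas = character(),
                            stringsAsFactors = FALSE)
  }
  rownames(stressors) <- NULL

  structure(list(
    key_events = key_events,
    annotations = ann,
    kers = kers,
    stressors = stressors,
    unresolved_refs = unresolved,
    source_version = source_version,
    namespace = ns_uri
  ), class = "aopwiki_dataset")
}

# Vectorised strip_markup.
strip_markup_v <- function(x) vapply(x, strip_markup, character(1L), USE.NAMES = FALSE)

`%|NA|%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

# read_xml with gzip sniffing by magic bytes (1f 8b).
read_xml_any <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    con <- gzfile(path, open = "rb")
    on.exit(close(con))
    raw <- readBin(con, "raw", n = 64L * 1024L * 1024L)
    xml2::read_xml(raw)
  } else {
    xml2::read_xml(path)
  }
}

#' @export
print.aopwiki_dataset <- function(x, ...) {
  cat("AOP-Wiki dataset", if (nzchar(x$source_version)) paste0("(", x$source_version, ")"), "\n")
  lv <- table(factor(x$key_events$level, levels = AOP_LEVELS))
  cat(sprintf("  key events: %d (%s)\n", nrow(x$key_events),
              paste(sprintf("%s=%d", names(lv)[lv > 0], lv[lv > 0]), collapse = ", ")))
  cat(sprintf("  key event relationships: %d (%d unresolved endpoint refs)\n",
              nrow(x$kers), nrow(x$unresolved_refs)))
  cat(sprintf("  stressor-chemical records: %d\n", nrow(x$stressors)))
  cat(sprintf("  ontology annotations: %d\n", nrow(x$annotations)))
  invisible(x)
}

#' Filter key events by biological-organization level
#'
#' @param dataset an `aopwiki_dataset`.
#' @param levels character vector of levels to keep; a non-empty subset of
#'   `molecular, cellular, tissue, organ, individual, population,
#'   unspecified`. Defaults to the four levels the linkage analysis targets.
#' @return the `key_events` data frame restricted to the requested levels,
#'   in dataset order.
#' @export
filter_key_events <- function(dataset, levels = IN_SCOPE_LEVELS) {
  stopifnot(inherits(dataset, "aopwiki_dataset"))
  if (length(levels) == 0L) {
    stop("'levels' must be a non-empty set of biological-organization levels",
         call. = FALSE)
  }
  bad <- setdiff(levels, AOP_LEVELS)
  if (length(bad)) {
    stop("unknown level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dataset$key_events[dataset$key_events$level %in% levels, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract stressor chemicals and dedicated summary counts
#'
#' Deduplicates chemicals by name and CAS registry numbers by their
#' normalized (trimmed, hyphenated) string. Records with an empty CAS are
#' retained in the collection but excluded from the unique-CAS count.
#'
#' @param dataset an `aopwiki_dataset`.
#' @return a list with `chemicals` (the stressor-chemical data frame),
#'   `n_stressors`, `n_unique_chemicals`, `n_unique_cas`.
#' @export
extract_chemicals <- function(dataset) {
  stopifnot(inherits(dataset, "aopwiki_dataset"))
  st <- dataset$stressors
  list(
    chemicals = st,
    n_stressors = length(unique(st$stressor_id)),
    n_unique_chemicals = length(unique(st$chemical_name[nzchar(st$chemical_name)])),
    n_unique_cas = length(unique(st$cas[nzchar(st$cas)]))
  )
}

#' Audit ontology-annotation usage of key events
#'
#' For each (level, component) pair, counts the KEs annotated with each
#' ontology source plus the KEs carrying no annotation for that component. A
#' KE with several annotations from one source counts once for that source;
#' a KE annotated from two sources for one component counts once per source,
#' so per-(level, component) source counts plus the unannotated count can
#' exceed the number of KEs at the level.
#'
#' @param dataset an `aopwiki_dataset`.
#' @param levels levels to include (default: molecular, cellular, tissue, organ).
#' @return a data frame with columns `level`, `component`, `source`,
#'   `n_kes`; rows with `source == "unannotated"` carry the unannotated-KE
#'   count for that (level, component).
#' @export
ontology_usage_summary <- function(dataset, levels = IN_SCOPE_LEVELS) {
  kes <- filter_key_events(dataset, levels)
  ann <- dataset$annotations[dataset$annotations$ke_id %in% kes$ke_id, , drop = FALSE]
  ann$level <- kes$level[match(ann$ke_id, kes$ke_id)]
  out <- list()
  for (lv in levels) {
    lv_kes <- kes$ke_id[kes$level == lv]
    for (comp in ANNOTATION_COMPONENTS) {
      sub <- ann[ann$level == lv & ann$component == comp, , drop = FALSE]
      if (nrow(sub)) {
        per_source <- tapply(sub$ke_id, sub$source, function(k) length(unique(k)))
        out[[length(out) + 1L]] <- data.frame(
          level = lv, component = comp, source = names(per_source),
          n_kes = as.integer(per_source), stringsAsFactors = FALSE)
      }
      n_unann <- length(setdiff(lv_kes, sub$ke_id))
      out[[length(out) + 1L]] <- data.frame(
        level = lv, component = comp, source = "unannotated",
        n_kes = n_unann, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$level, res$component, res$source), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Summary counts for the parse-stats CLI subcommand.
parse_stats <- function(dataset) {
  chem <- extract_chemicals(dataset)
  by_level <- table(factor(dataset$key_events$level, levels = AOP_LEVELS))
  list(
    stressors = chem$n_stressors,
    chemicals = chem$n_unique_chemicals,
    cas_numbers = chem$n_unique_cas,
    key_events_total = nrow(dataset$key_events),
    key_events_by_level = stats::setNames(as.list(as.integer(by_level)), names(by_level)),
    kers = nrow(dataset$kers)
  )
}
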