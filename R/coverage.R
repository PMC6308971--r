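# Assembly of all linkage stages into the headline coverage report.

.REPORT_COUNT_FIELDS <- c(
  "stressors", "chemicals", "cas_numbers", "cas_mapped", "chebi_ids",
  "chebi_in_pathways", "chem_pathways_hit", "kes_total", "kes_with_genes",
  "genes_in_kes", "genes_in_kes_covered", "kers_total", "genes_in_kers",
  "genes_in_kers_covered")

new_coverage_report <- function(counts, provenance = NULL) {
  stopifnot(setequal(names(counts), .REPORT_COUNT_FIELDS))
  counts <- lapply(counts[.REPORT_COUNT_FIELDS], as.integer)
  stopifnot(counts$cas_mapped <= counts$cas_numbers,
            counts$chebi_in_pathways <= counts$chebi_ids,
            counts$genes_in_kes_covered <= counts$genes_in_kes,
            counts$genes_in_kers_covered <= counts$genes_in_kers)
  structure(list(counts = counts,
                 provenance = provenance %||% run_provenance()),
            class = "coverage_report")
}

# Percent fields are always recomputed from the counts (round half up),
# never stored; NA when the denominator is zero.
coverage_report_values <- function(report) {
  ct <- report$counts
  c(ct[c("stressors", "chemicals", "cas_numbers", "cas_mapped", "chebi_ids",
         "chebi_in_pathways", "chem_pathways_hit", "kes_total",
         "kes_with_genes", "genes_in_kes", "genes_in_kes_covered")],
    list(pct_ke_genes_covered = pct_of(ct$genes_in_kes_covered, ct$genes_in_kes)),
    ct[c("kers_total", "genes_in_kers", "genes_in_kers_covered")],
    list(pct_ker_genes_covered = pct_of(ct$genes_in_kers_covered, ct$genes_in_kers)))
}

# Raw fractions retained alongside the integer percent display. The
# chemical coverage is given against all three defensible denominators
# (unique ChEBI IDs, unique CAS numbers, unique chemicals) because the
# source counts support all three readings.
coverage_report_raw <- function(report) {
  ct <- report$counts
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(
    ke_gene_coverage = frac(ct$genes_in_kes_covered, ct$genes_in_kes),
    ker_gene_coverage = frac(ct$genes_in_kers_covered, ct$genes_in_kers),
    cas_mapped_fraction = frac(ct$cas_mapped, ct$cas_numbers),
    chem_coverage_of_chebi = frac(ct$chebi_in_pathways, ct$chebi_ids),
    chem_coverage_of_cas = frac(ct$chebi_in_pathways, ct$cas_numbers),
    chem_coverage_of_chemicals = frac(ct$chebi_in_pathways, ct$chemicals)
  )
}

#' Build the AOP-pathway coverage report
#'
#' Runs the full linkage pipeline: chemical extraction and CAS-to-ChEBI
#' mapping resolved against pathway metabolites (hard linkage); key-event
#' filtering, gene-mention recognition and pathway coverage of the
#' recognised genes; the same for key-event relationships restricted to
#' in-scope levels (soft linkage). Deterministic given its inputs.
#'
#' @param dataset an `aopwiki_dataset`.
#' @param mapper a `cas_chebi_map`.
#' @param lexicon a `gene_lexicon`.
#' @param pathway_db a `pathway_db`.
#' @param levels biological-organization levels in scope (default molecular,
#'   cellular, tissue, organ).
#' @param provenance optional provenance block (see the CLI); defaults to
#'   tool version + timestamp.
#' @return an object of class `coverage_report`. The integer percent fields
#'   in its serialized form are recomputed half-up from the stored counts.
#' @export
build_coverage_report <- function(dataset, mapper, lexicon, pathway_db,
                                  levels = IN_SCOPE_LEVELS, provenance = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  chem <- stage("extract_chemicals", extract_chemicals(dataset))
  cm <- stage("map_chemicals", map_chemicals(mapper, chem$chemicals, pathway_db))
  kes <- stage("filter_key_events", filter_key_events(dataset, levels))
  ke_genes <- stage("map_genes_in_key_events", map_genes_in_key_events(kes, lexicon))
  ke_cov <- stage("genes_pathway_coverage",
                  genes_pathway_coverage(ke_genes$genes_total, pathway_db, lexicon))
  kers <- stage("restrict_kers_to_levels", restrict_kers_to_levels(dataset, levels))
  ker_genes <- stage("map_genes_in_kers", map_genes_in_kers(kers, lexicon))
  ker_cov <- stage("genes_pathway_coverage",
                   genes_pathway_coverage(ker_genes$genes_total, pathway_db, lexicon))
  new_coverage_report(list(
    stressors = chem$n_stressors,
    chemicals = chem$n_unique_chemicals,
    cas_numbers = chem$n_unique_cas,
    cas_mapped = cm$n_cas_mapped,
    chebi_ids = length(cm$chebi_ids),
    chebi_in_pathways = length(cm$chebi_in_pathways),
    chem_pathways_hit = length(cm$pathways_hit),
    kes_total = nrow(kes),
    kes_with_genes = ke_genes$kes_with_genes,
    genes_in_kes = length(ke_genes$genes_total),
    genes_in_kes_covered = length(ke_cov$covered),
    kers_total = nrow(kers),
    genes_in_kers = length(ker_genes$genes_total),
    genes_in_kers_covered = length(ker_cov$covered)
  ), provenance = provenance)
}

#' @export
print.coverage_report <- function(x, ...) {
  v <- coverage_report_values(x)
  cat("AOP-pathway coverage report\n")
  cat(sprintf("  stressors/chemicals/CAS: %d / %d / %d\n",
              v$stressors, v$chemicals, v$cas_numbers))
  cat(sprintf("  CAS mapped: %d -> %d ChEBI IDs, %d in pathways (%d pathways hit)\n",
              v$cas_mapped, v$chebi_ids, v$chebi_in_pathways, v$chem_pathways_hit))
  cat(sprintf("  KEs in scope: %d, with genes: %d, genes: %d, covered: %d (%s%%)\n",
              v$kes_total, v$kes_with_genes, v$genes_in_kes,
              v$genes_in_kes_covered,
              if (is.na(v$pct_ke_genes_covered)) "-" else v$pct_ke_genes_covered))
  cat(sprintf("  KERs in scope: %d, genes: %d, covered: %d (%s%%)\n",
              v$kers_total, v$genes_in_kers, v$genes_in_kers_covered,
              if (is.na(v$pct_ker_genes_covered)) "-" else v$pct_ker_genes_covered))
  invisible(x)
}

# NA percents/fractions serialize as JSON null (write_json_stable na rule).
report_to_json_list <- function(report) {
  c(coverage_report_values(report),
    list(raw = coverage_report_raw(report), provenance = report$provenance))
}

# Structural validation of a coverage-report JSON object against the
# contract shipped in inst/schema/coverage_report.schema.json.
validate_report_list <- function(obj) {
  required <- c(.REPORT_COUNT_FIELDS, "pct_ke_genes_covered",
                "pct_ker_genes_covered", "raw", "provenance")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("coverage report JSON missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in .REPORT_COUNT_FIELDS) {
    if (!is.numeric(obj[[f]]) || length(obj[[f]]) != 1L || obj[[f]] < 0) {
      stop(sprintf("coverage report field '%s' must be a non-negative number", f),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a coverage report to JSON or TSV
#'
#' JSON output carries the count fields, the recomputed integer percent
#' fields (null when undefined), a `raw` block with the underlying
#' fractions, and a `provenance` block; it validates against the JSON
#' Schema shipped at `system.file("schema", "coverage_report.schema.json",
#' package = "aoplink")`. TSV output is a two-column (metric, value) table
#' in fixed metric order. A write/read round trip reproduces the report's
#' counts exactly.
#'
#' @param report a `coverage_report`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_coverage_report()]
#' @export
write_coverage_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "coverage_report"))
  if (format == "json") {
    obj <- report_to_json_list(report)
    validate_report_list(obj)
    write_json_stable(obj, path)
  } else {
    v <- coverage_report_values(report)
    lines <- c("metric\tvalue",
               vapply(names(v), function(n) {
                 val <- v[[n]]
                 paste0(n, "\t", if (is.na(val)) "NA" else as.character(val))
               }, character(1L)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

#' Read a coverage report written by [write_coverage_report()]
#'
#' @param path a JSON or TSV report file; the format is inferred from the
#'   extension.
#' @return a `coverage_report`.
#' @export
read_coverage_report <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    validate_report_list(obj)
    new_coverage_report(obj[.REPORT_COUNT_FIELDS],
                        provenance = obj$provenance)
  } else {
    df <- utils::read.delim(path, colClasses = "character")
    vals <- stats::setNames(df$value, df$metric)
    new_coverage_report(as.list(as.integer(vals[.REPORT_COUNT_FIELDS])) |>
                          stats::setNames(.REPORT_COUNT_FIELDS))
  }
}
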