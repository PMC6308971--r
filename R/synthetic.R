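# Deterministic synthetic fixture bundles with a ground-truth manifest, so
# every pipeline stage has an exact oracle. The generator emulates the
# statistical shape of the real inputs -- an AOP-Wiki XML dump with planted
# gene mentions and decoy text, stressors with valid/invalid and
# mappable/unmappable CAS numbers, an HGNC-style lexicon, and a pathway
# database in which a controlled fraction of planted genes and metabolites
# appear -- not their biological content.

# Vocabulary used to build approved names and multi-word synonyms. Kept
# disjoint from the decoy/template vocabulary below so that certified
# collision-free bundles are possible by construction.
.NAME_WORDS <- c("putative", "transmembrane", "regulator", "kinase", "oxidase",
                 "reductase", "subunit", "homolog", "interacting", "carrier",
                 "channel", "effector", "adaptor", "scaffold", "ligase")

# Decoy sentences: free of every word in .NAME_WORDS, free of digits, and
# screened at generation time against the generated lexicon.
.DECOY_POOL <- c(
  "Exposure to the compound disrupts normal signalling in hepatic cells.",
  "A dose dependent increase in cellular damage was observed across replicates.",
  "The response was measured in treated animals after repeated exposure.",
  "Histological examination revealed marked changes in the affected organ.",
  "Sustained perturbation of this process leads to impaired function.",
  "No remarkable findings were reported for the control group.",
  "The event is considered an early indicator of downstream toxicity.",
  "Prolonged stress results in depletion of cellular reserves.",
  "Inflammation and swelling of the surrounding area were documented.",
  "Recovery was incomplete following withdrawal of the test substance."
)

.PLANT_TEMPLATES <- c(
  "Experimental evidence implicates %s in this biological event.",
  "Altered activity of %s accompanies the perturbation.",
  "Measurements showed strong involvement of %s during the response."
)

#' Create a synthetic-bundle configuration
#'
#' Defaults describe a desk-scale study: a few dozen key events across all
#' six biological-organization levels, a 60-gene lexicon, 15 stressors with
#' mostly valid and mostly mappable CAS numbers, and coverage targets of
#' 0.70 for genes and 0.16 for metabolites -- the shape of the coverage the
#' linkage analysis is designed to measure.
#'
#' @param seed integer RNG seed (mandatory; the same seed and config produce
#'   a byte-identical bundle).
#' @param n_kes_by_level named integer vector of KE counts per level.
#' @param n_kers number of key event relationships.
#' @param genes_per_ke planted genes per in-scope KE: a single count or a
#'   `c(min, max)` range.
#' @param n_lexicon_genes lexicon size.
#' @param fraction_forms_multiword fraction of synonyms that are multi-word.
#' @param n_stressors stressor entities.
#' @param fraction_cas_valid fraction of CAS numbers with a correct check digit.
#' @param fraction_cas_mappable fraction of CAS numbers present in the
#'   CAS-to-ChEBI table.
#' @param chebi_per_cas maximum ChEBI identifiers per mapped CAS.
#' @param n_pathways pathway count.
#' @param gene_coverage_target fraction of planted (in-scope) genes placed
#'   in pathways.
#' @param metabolite_coverage_target fraction of mapped ChEBI identifiers
#'   placed in pathways.
#' @param annotation_source_mix named weights over ontology sources used for
#'   KE annotations.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_kes_by_level = c(molecular = 12L, cellular = 10L,
                                                tissue = 5L, organ = 5L,
                                                individual = 4L, population = 2L),
                             n_kers = 20L,
                             genes_per_ke = c(0L, 3L),
                             n_lexicon_genes = 60L,
                             fraction_forms_multiword = 0.3,
                             n_stressors = 15L,
                             fraction_cas_valid = 0.9,
                             fraction_cas_mappable = 0.95,
                             chebi_per_cas = 2L,
                             n_pathways = 12L,
                             gene_coverage_target = 0.7,
                             metabolite_coverage_target = 0.16,
                             annotation_source_mix = c(GO = 0.5, CHEBI = 0.2,
                                                       PR = 0.15, UBERON = 0.1,
                                                       MESH = 0.05)) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_kes_by_level = n_kes_by_level,
              n_kers = as.integer(n_kers),
              genes_per_ke = as.integer(genes_per_ke),
              n_lexicon_genes = as.integer(n_lexicon_genes),
              fraction_forms_multiword = fraction_forms_multiword,
              n_stressors = as.integer(n_stressors),
              fraction_cas_valid = fraction_cas_valid,
              fraction_cas_mappable = fraction_cas_mappable,
              chebi_per_cas = as.integer(chebi_per_cas),
              n_pathways = as.integer(n_pathways),
              gene_coverage_target = gene_coverage_target,
              metabolite_coverage_target = metabolite_coverage_target,
              annotation_source_mix = annotation_source_mix)
  ratios <- c(cfg$fraction_forms_multiword, cfg$fraction_cas_valid,
              cfg$fraction_cas_mappable, cfg$gene_coverage_target,
              cfg$metabolite_coverage_target)
  if (any(ratios < 0 | ratios > 1)) stop("all ratios must be in [0, 1]", call. = FALSE)
  counts <- c(cfg$n_kes_by_level, cfg$n_kers, cfg$n_lexicon_genes,
              cfg$n_stressors, cfg$chebi_per_cas, cfg$n_pathways)
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  bad_lv <- setdiff(names(cfg$n_kes_by_level), AOP_LEVELS)
  if (length(bad_lv)) stop("unknown level(s) in n_kes_by_level: ",
                           paste(bad_lv, collapse = ", "), call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

rand_letters <- function(n) paste(sample(LETTERS, n, replace = TRUE), collapse = "")

# Independent surface-form scanner used only to certify generated text.
# Regex-based (boundary-guarded patterns per form), deliberately sharing no
# code with the tokenizing matcher in find_gene_mentions().
scan_text_for_forms <- function(text, forms) {
  hits <- character()
  for (i in seq_len(nrow(forms))) {
    form <- forms$form[[i]]
    toks <- regmatches(form, gregexpr("[A-Za-z0-9-]+", form))[[1L]]
    if (!length(toks)) next
    core <- paste(vapply(toks, function(t)
      gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", t), character(1L)),
      collapse = "[^A-Za-z0-9-]+")
    pat <- paste0("(?<![A-Za-z0-9-])", core, "(?![A-Za-z0-9-])")
    cs <- length(toks) == 1L &&
      forms$form_class[[i]] %in% c("approved_symbol", "previous_symbol", "synonym")
    if (grepl(pat, text, perl = TRUE, ignore.case = !cs)) {
      hits <- c(hits, forms$gene_id[[i]])
    }
  }
  sort(unique(hits))
}

#' Generate a synthetic fixture bundle
#'
#' Writes, under `out_dir`: `aopwiki.xml` (a dump in the dialect accepted by
#' [parse_aopwiki_xml()]), `lexicon.tsv`, `cas_chebi.tsv`, `pathways.tsv`,
#' one GPML 2013a file per pathway under `gpml/`, `pathways.ttl` (an RDF
#' rendering matched to [build_sparql_membership_query()]), and
#' `manifest.json`. The same seed and config yield byte-identical files.
#' Decoy text is screened against the generated lexicon and every assembled
#' description is verified to contain exactly its planted genes (an
#' independent regex scanner, not the pipeline matcher), so bundles are
#' certified collision-free. Errors before writing anything if a coverage
#' target is unattainable (a positive target with no pathways).
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `files` (named paths) and `manifest` (the
#'   ground-truth manifest, also serialized as `manifest.json`).
#' @seealso [expected_report()]
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # ---- lexicon -------------------------------------------------------------
  n_g <- config$n_lexicon_genes
  genes <- vector("list", n_g)
  used_syms <- character()
  for (i in seq_len(n_g)) {
    sym <- paste0(rand_letters(3L), i)
    prev <- if (i %% 3L == 0L) paste0(rand_letters(3L), "P", i) else ""
    n_syn <- sample(0:2, 1L)
    syns <- character()
    if (n_syn > 0L) {
      for (s in seq_len(n_syn)) {
        multi <- stats::runif(1) < config$fraction_forms_multiword
        syns <- c(syns, if (multi) {
          paste(sample(.NAME_WORDS, 1L), "variant", paste0(i, letters[s]))
        } else {
          paste0(rand_letters(2L), "S", i, LETTERS[s])
        })
      }
    }
    genes[[i]] <- list(
      gene_id = paste0("HGNC:", 10000L + i),
      approved_symbol = sym,
      approved_name = paste(paste(sample(.NAME_WORDS, 2L), collapse = " "), i),
      previous_symbols = prev,
      synonyms = paste(syns, collapse = "|"),
      ensembl_id = sprintf("ENSG%011d", i)
    )
    used_syms <- c(used_syms, sym)
  }
  lex_df <- do.call(rbind, lapply(genes, function(g)
    as.data.frame(g, stringsAsFactors = FALSE)))
  names(lex_df) <- c("gene_id", "approved_symbol", "approved_name",
                     "previous_symbols", "synonyms", "ensembl_id")

  # flat form table for the certification scanner
  forms_flat <- do.call(rbind, lapply(genes, function(g) {
    rows <- data.frame(gene_id = g$gene_id, form = g$approved_symbol,
                       form_class = "approved_symbol", stringsAsFactors = FALSE)
    rows <- rbind(rows, data.frame(gene_id = g$gene_id, form = g$approved_name,
                                   form_class = "approved_name", stringsAsFactors = FALSE))
    if (nzchar(g$previous_symbols)) {
      rows <- rbind(rows, data.frame(gene_id = g$gene_id, form = g$previous_symbols,
                                     form_class = "previous_symbol", stringsAsFactors = FALSE))
    }
    if (nzchar(g$synonyms)) {
      rows <- rbind(rows, data.frame(gene_id = g$gene_id,
                                     form = strsplit(g$synonyms, "|", fixed = TRUE)[[1L]],
                                     form_class = "synonym", stringsAsFactors = FALSE))
    }
    rows
  }))

  for (s in .DECOY_POOL) {
    bad <- scan_text_for_forms(s, forms_flat)
    if (length(bad)) {
      stop("decoy sentence collides with generated lexicon form(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  # ---- key events ----------------------------------------------------------
  lv_counts <- config$n_kes_by_level
  ke_levels <- rep(names(lv_counts), as.integer(lv_counts))
  n_ke <- length(ke_levels)
  ke_ids <- paste0("KE", seq_len(n_ke))

  # global shuffled queue of gene indices; refilled when exhausted, so
  # planted genes stay distinct until the pool is used up, and cross-KE
  # reuse begins only after that.
  queue <- sample.int(n_g)
  draw_genes <- function(k) {
    if (k == 0L) return(integer())
    out <- integer()
    while (length(out) < k) {
      if (!length(queue)) queue <<- sample.int(n_g)
      take <- setdiff(queue, out)
      if (!length(take)) { queue <<- sample.int(n_g); take <- setdiff(queue, out) }
      g <- take[[1L]]
      queue <<- queue[queue != g]
      out <- c(out, g)
    }
    out
  }

  plant_sentences <- function(gene_idx) {
    vapply(gene_idx, function(gi) {
      g <- genes[[gi]]
      pool <- c(g$approved_symbol, g$approved_name,
                if (nzchar(g$previous_symbols)) g$previous_symbols,
                if (nzchar(g$synonyms)) strsplit(g$synonyms, "|", fixed = TRUE)[[1L]])
      form <- sample(pool, 1L)
      sprintf(sample(.PLANT_TEMPLATES, 1L), form)
    }, character(1L))
  }

  gpk <- config$genes_per_ke
  ke_genes <- vector("list", n_ke)
  ke_desc <- character(n_ke)
  for (i in seq_len(n_ke)) {
    in_scope <- ke_levels[[i]] %in% IN_SCOPE_LEVELS
    k <- if (!in_scope) 0L
         else if (length(gpk) == 1L) gpk
         else sample(seq(gpk[[1L]], gpk[[2L]]), 1L)
    gi <- draw_genes(k)
    ke_genes[[i]] <- vapply(gi, function(j) genes[[j]]$gene_id, character(1L))
    sent <- c(sample(.DECOY_POOL, sample(1:2, 1L)), plant_sentences(gi))
    sent <- sample(sent)
    ke_desc[[i]] <- paste(sent, collapse = " ")
    found <- scan_text_for_forms(ke_desc[[i]], forms_flat)
    if (!setequal(found, ke_genes[[i]])) {
      stop(sprintf("planted-gene collision in %s: planted {%s}, scanner found {%s}",
                   ke_ids[[i]], paste(ke_genes[[i]], collapse = ","),
                   paste(found, collapse = ",")), call. = FALSE)
    }
  }

  # ---- KERs ----------------------------------------------------------------
  n_kers <- config$n_kers
  ker_fields <- c("description", "biological_plausibility", "empirical_support")
  kers <- vector("list", n_kers)
  for (i in seq_len(n_kers)) {
    pair <- sample.int(n_ke, 2L)
    both_in_scope <- all(ke_levels[pair] %in% IN_SCOPE_LEVELS)
    k <- if (both_in_scope) sample(0:2, 1L) else 0L
    gi <- draw_genes(k)
    field_of <- if (k > 0L) sample(ker_fields, k, replace = TRUE) else character()
    texts <- stats::setNames(vector("list", 3L), ker_fields)
    planted <- stats::setNames(vector("list", 3L), ker_fields)
    for (f in ker_fields) {
      sel <- which(field_of == f)
      planted[[f]] <- vapply(gi[sel], function(j) genes[[j]]$gene_id, character(1L))
      sent <- c(if (stats::runif(1) < 0.8) sample(.DECOY_POOL, 1L),
                plant_sentences(gi[sel]))
      texts[[f]] <- paste(sent, collapse = " ")
      found <- scan_text_for_forms(texts[[f]], forms_flat)
      if (!setequal(found, planted[[f]])) {
        stop("planted-gene collision in KER text", call. = FALSE)
      }
    }
    kers[[i]] <- list(ker_id = paste0("KER", i),
                      upstream_ke = ke_ids[[pair[[1L]]]],
                      downstream_ke = ke_ids[[pair[[2L]]]],
                      texts = texts, planted = planted)
  }

  # ---- stressors and CAS ---------------------------------------------------
  n_st <- config$n_stressors
  n_chem <- max(1L, round_half_up(0.8 * n_st))
  n_chem <- min(n_chem, n_st)
  # chemical n_chem (when there are >= 3) carries no CAS
  no_cas_idx <- if (n_chem >= 3L) n_chem else integer()
  cas_strings <- character(n_chem)
  n_with_cas <- n_chem - length(no_cas_idx)
  n_valid <- round_half_up(config$fraction_cas_valid * n_with_cas)
  valid_flags <- rep(FALSE, n_chem)
  with_cas <- setdiff(seq_len(n_chem), no_cas_idx)
  valid_flags[with_cas[seq_len(n_valid)]] <- TRUE
  for (i in with_cas) {
    repeat {
      body <- c(sample(1:9, 1L), sample(0:9, sample(3:6, 1L), replace = TRUE))
      mid <- sample(0:9, 2L, replace = TRUE)
      all_body <- c(body, mid)
      check <- cas_check_digit(all_body)
      if (!valid_flags[[i]]) check <- (check + 1L) %% 10L
      cand <- sprintf("%s-%s-%d", paste(body, collapse = ""),
                      paste(mid, collapse = ""), check)
      if (!cand %in% cas_strings) { cas_strings[[i]] <- cand; break }
    }
  }
  chem_names <- sprintf("test compound %d", seq_len(n_chem))
  st_chem <- c(seq_len(n_chem),
               if (n_st > n_chem) sample.int(n_chem, n_st - n_chem, replace = TRUE))
  stressors <- data.frame(
    stressor_id = paste0("ST", seq_len(n_st)),
    stressor_name = sprintf("stressor agent %d", seq_len(n_st)),
    chemical_name = chem_names[st_chem],
    cas = cas_strings[st_chem],
    stringsAsFactors = FALSE)

  uniq_cas <- cas_strings[with_cas]
  n_map <- round_half_up(config$fraction_cas_mappable * length(uniq_cas))
  mappable <- sort(sample(seq_along(uniq_cas), n_map))
  chebi_counter <- 50000L
  cas_chebi <- list()
  cas_to_chebi <- stats::setNames(vector("list", length(uniq_cas)), uniq_cas)
  for (j in mappable) {
    nc <- sample(seq_len(max(1L, config$chebi_per_cas)), 1L)
    ids <- sprintf("CHEBI:%d", chebi_counter + seq_len(nc))
    chebi_counter <- chebi_counter + nc
    cas_to_chebi[[j]] <- ids
    cas_chebi[[length(cas_chebi) + 1L]] <- data.frame(cas = uniq_cas[[j]], chebi = ids,
                                                      stringsAsFactors = FALSE)
  }
  # background mapping rows for CAS absent from the dump
  for (b in seq_len(3L)) {
    repeat {
      body <- c(sample(1:9, 1L), sample(0:9, 4L, replace = TRUE))
      mid <- sample(0:9, 2L, replace = TRUE)
      cand <- sprintf("%s-%s-%d", paste(body, collapse = ""),
                      paste(mid, collapse = ""), cas_check_digit(c(body, mid)))
      if (!cand %in% cas_strings) break
    }
    cas_chebi[[length(cas_chebi) + 1L]] <- data.frame(
      cas = cand, chebi = sprintf("CHEBI:%d", 90000L + b), stringsAsFactors = FALSE)
  }
  cas_chebi_df <- do.call(rbind, cas_chebi) %||%
    data.frame(cas = character(), chebi = character(), stringsAsFactors = FALSE)

  # ---- pathway placement ---------------------------------------------------
  in_scope_ke <- ke_levels %in% IN_SCOPE_LEVELS
  planted_ke_genes <- sort(unique(unlist(ke_genes[in_scope_ke], use.names = FALSE)))
  planted_ker_genes <- sort(unique(unlist(lapply(kers, function(k)
    unlist(k$planted, use.names = FALSE)), use.names = FALSE)))
  planted_union <- sort(unique(c(planted_ke_genes, planted_ker_genes)))
  n_gene_cov <- round_half_up(config$gene_coverage_target * length(planted_union))
  mapped_chebi <- sort(unique(unlist(cas_to_chebi, use.names = FALSE)))
  n_met_cov <- round_half_up(config$metabolite_coverage_target * length(mapped_chebi))
  if ((n_gene_cov > 0L || n_met_cov > 0L) && config$n_pathways == 0L) {
    stop("coverage targets unattainable: positive coverage requested but n_pathways = 0",
         call. = FALSE)
  }

  covered_genes <- if (n_gene_cov > 0L) sort(sample(planted_union, n_gene_cov)) else character()
  covered_chebi <- if (n_met_cov > 0L) sort(sample(mapped_chebi, n_met_cov)) else character()

  n_pw <- config$n_pathways
  pw_ids <- paste0("WP", seq_len(n_pw))
  gene_sym <- stats::setNames(lex_df$approved_symbol, lex_df$gene_id)
  gene_ens <- stats::setNames(lex_df$ensembl_id, lex_df$gene_id)
  pw_rows <- list()
  gene_pathways <- stats::setNames(vector("list", length(covered_genes)), covered_genes)
  for (k in seq_along(covered_genes)) {
    g <- covered_genes[[k]]
    pw <- pw_ids[[((k - 1L) %% n_pw) + 1L]]
    gene_pathways[[g]] <- pw
    ns <- if (k %% 5L == 0L) "HGNC_ID" else "HGNC_SYMBOL"
    id <- if (ns == "HGNC_ID") g else gene_sym[[g]]
    pw_rows[[length(pw_rows) + 1L]] <- data.frame(
      pathway_id = pw, namespace = ns, xref_id = id, stringsAsFactors = FALSE)
    if (k %% 3L == 0L) {
      pw_rows[[length(pw_rows) + 1L]] <- data.frame(
        pathway_id = pw, namespace = "ENSEMBL", xref_id = gene_ens[[g]],
        stringsAsFactors = FALSE)
    }
  }
  # a couple of lexicon genes present in pathways but never planted in text
  extra <- setdiff(lex_df$gene_id, planted_union)
  if (length(extra) >= 2L && n_pw > 0L) {
    for (g in extra[1:2]) {
      pw_rows[[length(pw_rows) + 1L]] <- data.frame(
        pathway_id = pw_ids[[1L]], namespace = "HGNC_SYMBOL",
        xref_id = gene_sym[[g]], stringsAsFactors = FALSE)
    }
  }
  met_pathways <- stats::setNames(vector("list", length(covered_chebi)), covered_chebi)
  met_rows <- list()
  for (k in seq_along(covered_chebi)) {
    ch <- covered_chebi[[k]]
    pws <- pw_ids[unique(c(((k - 1L) %% n_pw) + 1L,
                           if (k %% 4L == 0L) ((k) %% n_pw) + 1L))]
    met_pathways[[ch]] <- sort(pws)
    for (pw in pws) {
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        pathway_id = pw, chebi = ch, stringsAsFactors = FALSE)
    }
  }
  pw_tags <- list()
  for (k in seq_len(n_pw)) {
    if (stats::runif(1) < 0.6) pw_tags[[length(pw_tags) + 1L]] <- data.frame(
      pathway_id = pw_ids[[k]], source = "PW",
      term_id = sprintf("PW:%07d", k), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.2) pw_tags[[length(pw_tags) + 1L]] <- data.frame(
      pathway_id = pw_ids[[k]], source = "CL",
      term_id = sprintf("CL:%07d", k), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.3) pw_tags[[length(pw_tags) + 1L]] <- data.frame(
      pathway_id = pw_ids[[k]], source = "DO",
      term_id = sprintf("DOID:%d", 1000L + k), stringsAsFactors = FALSE)
  }
  gene_xref_df <- do.call(rbind, pw_rows) %||%
    data.frame(pathway_id = character(), namespace = character(),
               xref_id = character(), stringsAsFactors = FALSE)
  met_xref_df <- do.call(rbind, met_rows) %||%
    data.frame(pathway_id = character(), chebi = character(), stringsAsFactors = FALSE)
  tag_df <- do.call(rbind, pw_tags) %||%
    data.frame(pathway_id = character(), source = character(),
               term_id = character(), stringsAsFactors = FALSE)

  # ---- KE ontology annotations ---------------------------------------------
  mix <- config$annotation_source_mix
  ann_rows <- list()
  term_for_source <- function(src, k) {
    switch(src,
           GO = sprintf("GO:%07d", k),
           CHEBI = sprintf("CHEBI:%d", 16000L + k),
           PR = sprintf("PR:%09d", k),
           UBERON = sprintf("UBERON:%07d", k),
           MESH = sprintf("MESH:D%06d", k),
           sprintf("%s:%07d", src, k))
  }
  for (i in seq_len(n_ke)) {
    if (!in_scope_ke[[i]] || stats::runif(1) >= 0.6) next
    comps <- sample(ANNOTATION_COMPONENTS, sample(1:2, 1L))
    for (comp in comps) {
      src <- sample(names(mix), 1L, prob = mix)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        ke_id = ke_ids[[i]], component = comp, source = src,
        term_id = term_for_source(src, i),
        term_label = sprintf("synthetic term %d", i), stringsAsFactors = FALSE)
    }
  }
  ann_df <- do.call(rbind, ann_rows) %||%
    data.frame(ke_id = character(), component = character(), source = character(),
               term_id = character(), term_label = character(), stringsAsFactors = FALSE)

  # ---- manifest ------------------------------------------------------------
  manifest <- list(
    config = unclass(config),
    kes = lapply(seq_len(n_ke), function(i) list(
      ke_id = ke_ids[[i]], level = ke_levels[[i]],
      genes = as.list(sort(ke_genes[[i]])))),
    kers = lapply(kers, function(k) list(
      ker_id = k$ker_id, upstream_ke = k$upstream_ke,
      downstream_ke = k$downstream_ke,
      genes_by_field = lapply(k$planted, function(g) as.list(sort(g))))),
    stressors = stressors,
    cas = data.frame(cas = uniq_cas,
                     valid = valid_flags[with_cas],
                     mappable = seq_along(uniq_cas) %in% mappable,
                     stringsAsFactors = FALSE),
    cas_to_chebi = lapply(cas_to_chebi, as.list),
    n_chemicals = n_chem,
    gene_pathways = lapply(gene_pathways, as.list),
    metabolite_pathways = lapply(met_pathways, as.list),
    annotations = ann_df,
    pathway_tags = tag_df,
    pathway_ids = pw_ids,
    lexicon_gene_ids = lex_df$gene_id
  )
  manifest$expected_report <- unclass_report(expected_report(manifest))

  # ---- write files ---------------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "gpml"), showWarnings = FALSE)
  files <- c(xml = file.path(out_dir, "aopwiki.xml"),
             lexicon = file.path(out_dir, "lexicon.tsv"),
             cas_chebi = file.path(out_dir, "cas_chebi.tsv"),
             pathways = file.path(out_dir, "pathways.tsv"),
             ttl = file.path(out_dir, "pathways.ttl"),
             manifest = file.path(out_dir, "manifest.json"))

  write_lf <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  }

  # aopwiki.xml; half the descriptions carry embedded markup to exercise
  # the parser's stripping.
  xml <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           "<data xmlns=\"http://www.aopkb.org/aop-xml\" created=\"synthetic\">")
  for (i in seq_len(n_ke)) {
    desc <- xml_escape(ke_desc[[i]])
    if (i %% 2L == 0L) desc <- paste0("<p>", desc, "</p>")
    ann_i <- ann_df[ann_df$ke_id == ke_ids[[i]], , drop = FALSE]
    xml <- c(xml,
             sprintf("  <key-event id=\"%s\">", ke_ids[[i]]),
             sprintf("    <title>%s</title>", xml_escape(sprintf("Synthetic event %d", i))),
             sprintf("    <biological-organization-level>%s</biological-organization-level>",
                     # mixed case exercises case-insensitive level matching
                     if (i %% 2L == 0L) tools::toTitleCase(ke_levels[[i]]) else ke_levels[[i]]),
             sprintf("    <description>%s</description>", desc),
             if (nrow(ann_i)) sprintf(
               "    <ontology-annotation component=\"%s\" term-id=\"%s\" term-label=\"%s\"/>",
               ann_i$component, ann_i$term_id, xml_escape(ann_i$term_label)),
             "  </key-event>")
  }
  for (k in kers) {
    xml <- c(xml,
             sprintf("  <key-event-relationship id=\"%s\">", k$ker_id),
             sprintf("    <upstream-key-event>%s</upstream-key-event>", k$upstream_ke),
             sprintf("    <downstream-key-event>%s</downstream-key-event>", k$downstream_ke),
             sprintf("    <description>%s</description>", xml_escape(k$texts$description)),
             sprintf("    <biological-plausibility>%s</biological-plausibility>",
                     xml_escape(k$texts$biological_plausibility)),
             sprintf("    <empirical-support>%s</empirical-support>",
                     xml_escape(k$texts$empirical_support)),
             "  </key-event-relationship>")
  }
  for (sid in unique(stressors$stressor_id)) {
    rows <- stressors[stressors$stressor_id == sid, , drop = FALSE]
    xml <- c(xml,
             sprintf("  <stressor id=\"%s\">", sid),
             sprintf("    <name>%s</name>", xml_escape(rows$stressor_name[[1L]])),
             unlist(lapply(seq_len(nrow(rows)), function(r) {
               c(sprintf("    <chemical cas=\"%s\">", rows$cas[[r]]),
                 sprintf("      <name>%s</name>", xml_escape(rows$chemical_name[[r]])),
                 "    </chemical>")
             })),
             "  </stressor>")
  }
  xml <- c(xml, "</data>")
  write_lf(xml, files[["xml"]])

  tsv_line <- function(...) paste(..., sep = "\t")
  write_lf(c(tsv_line("hgnc_id", "approved_symbol", "approved_name",
                      "previous_symbols", "synonyms", "ensembl_id"),
             vapply(seq_len(nrow(lex_df)), function(i)
               tsv_line(lex_df$gene_id[[i]], lex_df$approved_symbol[[i]],
                        lex_df$approved_name[[i]], lex_df$previous_symbols[[i]],
                        lex_df$synonyms[[i]], lex_df$ensembl_id[[i]]),
               character(1L))),
           files[["lexicon"]])

  write_lf(c(tsv_line("cas", "chebi"),
             if (nrow(cas_chebi_df)) vapply(seq_len(nrow(cas_chebi_df)), function(i)
               tsv_line(cas_chebi_df$cas[[i]], cas_chebi_df$chebi[[i]]), character(1L))),
           files[["cas_chebi"]])

  pw_title <- stats::setNames(sprintf("synthetic pathway %d", seq_len(n_pw)), pw_ids)
  tsv_rows <- c(
    if (nrow(gene_xref_df)) vapply(seq_len(nrow(gene_xref_df)), function(i)
      tsv_line(gene_xref_df$pathway_id[[i]], pw_title[[gene_xref_df$pathway_id[[i]]]],
               gene_xref_df$namespace[[i]], gene_xref_df$xref_id[[i]]), character(1L)),
    if (nrow(met_xref_df)) vapply(seq_len(nrow(met_xref_df)), function(i)
      tsv_line(met_xref_df$pathway_id[[i]], pw_title[[met_xref_df$pathway_id[[i]]]],
               "CHEBI", met_xref_df$chebi[[i]]), character(1L)),
    if (nrow(tag_df)) vapply(seq_len(nrow(tag_df)), function(i)
      tsv_line(tag_df$pathway_id[[i]], pw_title[[tag_df$pathway_id[[i]]]],
               tag_df$source[[i]], tag_df$term_id[[i]]), character(1L)),
    # pathways with no xrefs at all still need a title-only row
    vapply(setdiff(pw_ids, c(gene_xref_df$pathway_id, met_xref_df$pathway_id,
                             tag_df$pathway_id)), function(pw)
      tsv_line(pw, pw_title[[pw]], "", ""), character(1L)))
  write_lf(c(tsv_line("pathway_id", "title", "xref_namespace", "xref_id"), tsv_rows),
           files[["pathways"]])

  gpml_files <- character()
  for (k in seq_len(n_pw)) {
    pw <- pw_ids[[k]]
    g <- gene_xref_df[gene_xref_df$pathway_id == pw, , drop = FALSE]
    m <- met_xref_df[met_xref_df$pathway_id == pw, , drop = FALSE]
    t <- tag_df[tag_df$pathway_id == pw, , drop = FALSE]
    db_of <- c(HGNC_SYMBOL = "HGNC", HGNC_ID = "HGNC Accession number",
               ENSEMBL = "Ensembl")
    lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               sprintf("<Pathway xmlns=\"%s\" Name=\"%s\" Version=\"1\">",
                       .GPML_NS_2013A, xml_escape(pw_title[[pw]])),
               if (nrow(g)) unlist(lapply(seq_len(nrow(g)), function(r)
                 c(sprintf("  <DataNode TextLabel=\"%s\" Type=\"GeneProduct\">",
                           xml_escape(g$xref_id[[r]])),
                   sprintf("    <Xref Database=\"%s\" ID=\"%s\"/>",
                           db_of[[g$namespace[[r]]]], g$xref_id[[r]]),
                   "  </DataNode>"))),
               if (nrow(m)) unlist(lapply(seq_len(nrow(m)), function(r)
                 c(sprintf("  <DataNode TextLabel=\"%s\" Type=\"Metabolite\">",
                           m$chebi[[r]]),
                   sprintf("    <Xref Database=\"ChEBI\" ID=\"%s\"/>", m$chebi[[r]]),
                   "  </DataNode>"))),
               if (nrow(t)) c("  <Biopax>",
                              unlist(lapply(t$term_id, function(term) c(
                                "    <bp:openControlledVocabulary xmlns:bp=\"http://www.biopax.org/release/biopax-level3.owl#\">",
                                sprintf("      <bp:ID>%s</bp:ID>", term),
                                "    </bp:openControlledVocabulary>"))),
                              "  </Biopax>"),
               "</Pathway>")
    p <- file.path(out_dir, "gpml", paste0(pw, ".gpml"))
    write_lf(lines, p)
    gpml_files <- c(gpml_files, p)
  }

  ttl <- c("@prefix wp: <http://vocabularies.wikipathways.org/wp#> .",
           "@prefix dcterms: <http://purl.org/dc/terms/> .",
           "@prefix dc: <http://purl.org/dc/elements/1.1/> .",
           "")
  pred_of <- c(HGNC_SYMBOL = "wp:bdbHgncSymbol", HGNC_ID = "wp:bdbHgnc",
               ENSEMBL = "wp:bdbEnsembl")
  iri_of <- function(ns, id) {
    base <- c(HGNC_SYMBOL = "http://identifiers.org/hgnc.symbol/",
              HGNC_ID = "http://identifiers.org/hgnc/",
              ENSEMBL = "http://identifiers.org/ensembl/")[[ns]]
    paste0("<", base, id, ">")
  }
  node_n <- 0L
  for (k in seq_len(n_pw)) {
    pw <- pw_ids[[k]]
    pw_iri <- sprintf("<http://identifiers.org/wikipathways/%s>", pw)
    ttl <- c(ttl, sprintf("%s a wp:Pathway ; dc:title \"%s\" .", pw_iri, pw_title[[pw]]))
    g <- gene_xref_df[gene_xref_df$pathway_id == pw, , drop = FALSE]
    for (r in seq_len(nrow(g))) {
      node_n <- node_n + 1L
      ttl <- c(ttl, sprintf("<http://example.org/node/%d> dcterms:isPartOf %s ; %s %s .",
                            node_n, pw_iri, pred_of[[g$namespace[[r]]]],
                            iri_of(g$namespace[[r]], g$xref_id[[r]])))
    }
    m <- met_xref_df[met_xref_df$pathway_id == pw, , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      node_n <- node_n + 1L
      ttl <- c(ttl, sprintf(
        "<http://example.org/node/%d> dcterms:isPartOf %s ; wp:bdbChEBI <http://identifiers.org/chebi/%s> .",
        node_n, pw_iri, m$chebi[[r]]))
    }
  }
  write_lf(ttl, files[["ttl"]])

  write_json_stable(manifest_to_json(manifest), files[["manifest"]])

  invisible(list(files = c(as.list(files), list(gpml = gpml_files)),
                 manifest = manifest))
}

# JSON-friendly rendering of the manifest (data frames -> row lists).
manifest_to_json <- function(m) {
  df_to_rows <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  cfg <- m$config[setdiff(names(m$config), "n_kes_by_level")]
  cfg$n_kes_by_level <- as.list(m$config$n_kes_by_level)
  cfg$annotation_source_mix <- as.list(m$config$annotation_source_mix)
  list(config = cfg,
       kes = m$kes,
       kers = m$kers,
       stressors = df_to_rows(m$stressors),
       cas = df_to_rows(m$cas),
       cas_to_chebi = m$cas_to_chebi,
       n_chemicals = m$n_chemicals,
       gene_pathways = m$gene_pathways,
       metabolite_pathways = m$metabolite_pathways,
       annotations = df_to_rows(m$annotations),
       pathway_tags = df_to_rows(m$pathway_tags),
       pathway_ids = as.list(m$pathway_ids),
       lexicon_gene_ids = as.list(m$lexicon_gene_ids),
       expected_report = m$expected_report)
}

unclass_report <- function(report) {
  coverage_report_values(report)
}

#' Recompute the expected coverage report from a ground-truth manifest
#'
#' Brute-force counting over the planted structures: set unions and
#' intersections over the manifest's planted gene sets, CAS/ChEBI tables
#' and pathway placements. Shares no code with the pipeline stages it
#' oracles -- no XML parsing, no tokenization, no table joins.
#'
#' @param manifest a manifest from [generate_bundle()] (the in-memory list
#'   or the result of reading `manifest.json`).
#' @param levels biological-organization levels in scope.
#' @return a `coverage_report`.
#' @export
expected_report <- function(manifest, levels = IN_SCOPE_LEVELS) {
  ke_levels <- vapply(manifest$kes, `[[`, character(1L), "level")
  ke_ids <- vapply(manifest$kes, `[[`, character(1L), "ke_id")
  in_scope <- ke_levels %in% levels
  ke_gene_sets <- lapply(manifest$kes, function(k) unlist(k$genes, use.names = FALSE) %||% character())
  genes_in_kes <- sort(unique(unlist(ke_gene_sets[in_scope], use.names = FALSE)))
  kes_with_genes <- sum(vapply(ke_gene_sets[in_scope], length, integer(1L)) > 0L)

  scope_ids <- ke_ids[in_scope]
  ker_in_scope <- vapply(manifest$kers, function(k)
    k$upstream_ke %in% scope_ids && k$downstream_ke %in% scope_ids, logical(1L))
  ker_gene_sets <- lapply(manifest$kers, function(k)
    sort(unique(unlist(k$genes_by_field, use.names = FALSE) %||% character())))
  genes_in_kers <- sort(unique(unlist(ker_gene_sets[ker_in_scope], use.names = FALSE)))

  placed <- names(manifest$gene_pathways)[
    vapply(manifest$gene_pathways, function(p) length(unlist(p)) > 0L, logical(1L))]
  st <- manifest$stressors
  if (!is.data.frame(st)) st <- do.call(rbind, lapply(st, as.data.frame))
  cas_tab <- manifest$cas
  if (!is.data.frame(cas_tab)) cas_tab <- do.call(rbind, lapply(cas_tab, as.data.frame))
  mapped_cas <- cas_tab$cas[cas_tab$mappable]
  chebi_ids <- sort(unique(unlist(manifest$cas_to_chebi, use.names = FALSE)))
  met_placed <- names(manifest$metabolite_pathways)[
    vapply(manifest$metabolite_pathways, function(p) length(unlist(p)) > 0L, logical(1L))]
  chebi_in_pw <- intersect(chebi_ids, met_placed)
  pw_hit <- sort(unique(unlist(manifest$metabolite_pathways[chebi_in_pw], use.names = FALSE)))

  new_coverage_report(list(
    stressors = length(unique(st$stressor_id)),
    chemicals = length(unique(st$chemical_name[nzchar(st$chemical_name)])),
    cas_numbers = length(unique(cas_tab$cas)),
    cas_mapped = length(unique(mapped_cas)),
    chebi_ids = length(chebi_ids),
    chebi_in_pathways = length(chebi_in_pw),
    chem_pathways_hit = length(pw_hit),
    kes_total = sum(in_scope),
    kes_with_genes = kes_with_genes,
    genes_in_kes = length(genes_in_kes),
    genes_in_kes_covered = length(intersect(genes_in_kes, placed)),
    kers_total = sum(ker_in_scope),
    genes_in_kers = length(genes_in_kers),
    genes_in_kers_covered = length(intersect(genes_in_kers, placed))
  ))
}
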