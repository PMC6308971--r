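# Soft linkage: dictionary-based gene-mention recognition over free text.

FORM_CLASSES <- c("approved_symbol", "previous_symbol", "synonym", "approved_name")

# Lower number wins when candidates tie on length and start position.
.form_class_priority <- c(approved_symbol = 1L, previous_symbol = 2L,
                          synonym = 3L, approved_name = 4L)

.KEY_SEP <- "\x1f"

#' Load an HGNC-style gene lexicon
#'
#' Compiles a surface-form dictionary from a tab-separated table in the
#' style of a genenames.org custom download: columns `hgnc_id`,
#' `approved_symbol`, `approved_name`, `previous_symbols`, `synonyms`,
#' `ensembl_id`, with multi-valued columns separated by commas or pipes.
#' Forms are stored verbatim (case preserved); single-character forms are
#' dropped (alphabet-letter false positives). The returned object carries an
#' ambiguity index of every surface form claimed by two or more genes under
#' the matching rules of [find_gene_mentions()].
#'
#' @param path lexicon TSV file.
#' @return an object of class `gene_lexicon` with `entries` (gene_id,
#'   approved_symbol, ensembl_id), `forms` (gene_id, form, form_class), and
#'   `ambiguity` (form, gene_ids comma-joined).
#' @export
load_gene_lexicon <- function(path) {
  req <- c("hgnc_id", "approved_symbol", "approved_name",
           "previous_symbols", "synonyms", "ensembl_id")
  df <- read_tsv_checked(path, req, "gene lexicon")
  if (anyDuplicated(df$hgnc_id)) {
    stop(sprintf("duplicate hgnc_id in lexicon: %s",
                 paste(unique(df$hgnc_id[duplicated(df$hgnc_id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(trimws(df$approved_symbol)))) {
    stop("every lexicon entry needs a non-empty approved_symbol", call. = FALSE)
  }
  split_multi <- function(x) {
    v <- trimws(strsplit(x, "[,|]")[[1L]])
    v[nzchar(v)]
  }
  forms <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    g <- df$hgnc_id[[i]]
    rows <- list(data.frame(gene_id = g, form = trimws(df$approved_symbol[[i]]),
                            form_class = "approved_symbol", stringsAsFactors = FALSE))
    nm <- trimws(df$approved_name[[i]])
    if (nzchar(nm)) {
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, form = nm,
                                              form_class = "approved_name",
                                              stringsAsFactors = FALSE)
    }
    prev <- split_multi(df$previous_symbols[[i]])
    if (length(prev)) {
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, form = prev,
                                              form_class = "previous_symbol",
                                              stringsAsFactors = FALSE)
    }
    syn <- split_multi(df$synonyms[[i]])
    if (length(syn)) {
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, form = syn,
                                              form_class = "synonym",
                                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }))
  if (is.null(forms)) {
    forms <- data.frame(gene_id = character(), form = character(),
                        form_class = character(), stringsAsFactors = FALSE)
  }
  forms <- forms[nchar(forms$form) >= 2L, , drop = FALSE]
  forms <- unique(forms)
  rownames(forms) <- NULL

  lex <- structure(list(
    entries = data.frame(gene_id = df$hgnc_id,
                         approved_symbol = trimws(df$approved_symbol),
                         ensembl_id = trimws(df$ensembl_id),
                         stringsAsFactors = FALSE),
    forms = forms
  ), class = "gene_lexicon")
  lex <- build_lexicon_index(lex)

  keys <- lex$forms$key
  amb_keys <- names(which(vapply(split(lex$forms$gene_id, keys),
                                 function(g) length(unique(g)) > 1L, logical(1L))))
  amb <- lex$forms[keys %in% amb_keys, , drop = FALSE]
  lex$ambiguity <- if (nrow(amb)) {
    agg <- lapply(split(amb$gene_id, amb$form), function(g) sort(unique(g)))
    data.frame(form = names(agg),
               gene_ids = vapply(agg, paste, character(1L), collapse = ","),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(form = character(), gene_ids = character(), stringsAsFactors = FALSE)
  }
  lex
}

# Attach the matching index: per form its token count, lookup key and case
# rule. Symbol-class single-token forms match case-sensitively; approved
# names and multi-token forms match case-insensitively as token sequences.
build_lexicon_index <- function(lex) {
  forms <- lex$forms
  tok <- lapply(forms$form, function(f) tokenize(f)$token)
  n_tokens <- lengths(tok)
  keep <- n_tokens > 0L
  forms <- forms[keep, , drop = FALSE]
  tok <- tok[keep]
  n_tokens <- n_tokens[keep]
  case_sensitive <- n_tokens == 1L &
    forms$form_class %in% c("approved_symbol", "previous_symbol", "synonym")
  key <- character(nrow(forms))
  key[case_sensitive] <- vapply(tok[case_sensitive], identity, character(1L))
  key[!case_sensitive] <- vapply(tok[!case_sensitive], function(t)
    paste(tolower(t), collapse = .KEY_SEP), character(1L))
  forms$n_tokens <- n_tokens
  forms$case_sensitive <- case_sensitive
  forms$key <- key
  rownames(forms) <- NULL

  env_cs <- new.env(parent = emptyenv())
  env_ci <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(forms))) {
    e <- if (forms$case_sensitive[[i]]) env_cs else env_ci
    k <- forms$key[[i]]
    e[[k]] <- c(e[[k]] %||% integer(), i)
  }
  lex$forms <- forms
  lex$index <- list(cs = env_cs, ci = env_ci,
                    max_tokens = max(c(1L, forms$n_tokens)))
  lex
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat(sprintf("Gene lexicon: %d genes, %d surface forms (%d ambiguous)\n",
              nrow(x$entries), nrow(x$forms), nrow(x$ambiguity)))
  invisible(x)
}

#' Find gene mentions in normalized free text
#'
#' Dictionary matching over text that has already been markup-stripped and
#' whitespace-normalized (the [parse_aopwiki_xml()] contract). Tokens are
#' maximal runs of letters, digits and hyphens, so "IL-6" is one token.
#' Symbol-class forms (approved/previous symbols, single-token synonyms)
#' match case-sensitively as whole tokens -- "CAT" the gene never matches
#' "cat" the word; approved names and multi-word synonyms match
#' case-insensitively as whole-token sequences. Overlapping candidates are
#' resolved longest-match-first, ties broken by leftmost start and then by
#' form-class priority (approved_symbol > previous_symbol > synonym >
#' approved_name); a matched span is consumed, so no nested matches. A form
#' claimed by several genes emits one mention per claiming gene, flagged
#' ambiguous.
#'
#' @param text a single character string.
#' @param lexicon a `gene_lexicon`.
#' @return data frame with columns `gene_id`, `matched_form`, `form_class`,
#'   `start`, `end` (0-based half-open offsets into `text`), `ambiguous`.
#' @export
find_gene_mentions <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "gene_lexicon"), length(text) == 1L)
  empty <- data.frame(gene_id = character(), matched_form = character(),
                      form_class = character(), start = integer(),
                      end = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  toks <- tokenize(text)
  n <- nrow(toks)
  if (n == 0L) return(empty)
  idx <- lexicon$index
  lower <- tolower(toks$token)

  cand <- list()
  for (L in seq_len(min(idx$max_tokens, n))) {
    for (i in seq_len(n - L + 1L)) {
      rows <- integer()
      if (L == 1L) {
        rows <- idx$cs[[toks$token[[i]]]] %||% integer()
      }
      k <- paste(lower[i:(i + L - 1L)], collapse = .KEY_SEP)
      rows <- c(rows, idx$ci[[k]] %||% integer())
      if (length(rows)) {
        cand[[length(cand) + 1L]] <- list(i = i, L = L, rows = rows)
      }
    }
  }
  if (!length(cand)) return(empty)

  best_prio <- vapply(cand, function(c)
    min(.form_class_priority[lexicon$forms$form_class[c$rows]]), numeric(1L))
  ord <- order(-vapply(cand, `[[`, integer(1L), "L"),
               vapply(cand, `[[`, integer(1L), "i"),
               best_prio)
  consumed <- logical(n)
  out <- list()
  for (c in cand[ord]) {
    span <- c$i:(c$i + c$L - 1L)
    if (any(consumed[span])) next
    consumed[span] <- TRUE
    rows <- c$rows
    genes <- lexicon$forms$gene_id[rows]
    amb <- length(unique(genes)) > 1L
    out[[length(out) + 1L]] <- data.frame(
      gene_id = genes,
      matched_form = lexicon$forms$form[rows],
      form_class = lexicon$forms$form_class[rows],
      start = toks$start[[c$i]],
      end = toks$end[[c$i + c$L - 1L]],
      ambiguous = amb,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Recognise genes across key-event descriptions
#'
#' @param kes a key-event data frame (typically from [filter_key_events()]).
#' @param lexicon a `gene_lexicon`.
#' @return list with `per_ke` (named list ke_id -> sorted unique gene_id
#'   vector), `genes_total` (union across KEs), `kes_with_genes` (count of
#'   KEs with a non-empty set), and `mentions` (row-bound mention table with
#'   a leading `ke_id` column).
#' @export
map_genes_in_key_events <- function(kes, lexicon) {
  per_ke <- stats::setNames(vector("list", nrow(kes)), kes$ke_id)
  mentions <- list()
  for (i in seq_len(nrow(kes))) {
    m <- find_gene_mentions(kes$description[[i]], lexicon)
    per_ke[[i]] <- sort(unique(m$gene_id))
    if (nrow(m)) {
      mentions[[length(mentions) + 1L]] <- cbind(
        data.frame(ke_id = kes$ke_id[[i]], stringsAsFactors = FALSE), m)
    }
  }
  list(
    per_ke = per_ke,
    genes_total = sort(unique(unlist(per_ke, use.names = FALSE))),
    kes_with_genes = sum(lengths(per_ke) > 0L),
    mentions = if (length(mentions)) do.call(rbind, mentions) else NULL
  )
}

#' Recognise genes across key-event-relationship texts
#'
#' Each KER contributes three text fields -- description, biological
#' plausibility and empirical support -- searched independently; the per-KER
#' gene set is their union.
#'
#' @param kers a KER data frame (see [parse_aopwiki_xml()]), typically
#'   restricted to KERs connecting in-scope key events.
#' @param lexicon a `gene_lexicon`.
#' @return list with `per_ker`, `genes_total`, `kers_with_genes`, `mentions`
#'   (mentions carry a `field` column naming the text field).
#' @export
map_genes_in_kers <- function(kers, lexicon) {
  fields <- c("description", "biological_plausibility", "empirical_support")
  per_ker <- stats::setNames(vector("list", nrow(kers)), kers$ker_id)
  mentions <- list()
  for (i in seq_len(nrow(kers))) {
    genes <- character()
    for (f in fields) {
      m <- find_gene_mentions(kers[[f]][[i]], lexicon)
      genes <- c(genes, m$gene_id)
      if (nrow(m)) {
        mentions[[length(mentions) + 1L]] <- cbind(
          data.frame(ker_id = kers$ker_id[[i]], field = f, stringsAsFactors = FALSE), m)
      }
    }
    per_ker[[i]] <- sort(unique(genes))
  }
  list(
    per_ker = per_ker,
    genes_total = sort(unique(unlist(per_ker, use.names = FALSE))),
    kers_with_genes = sum(lengths(per_ker) > 0L),
    mentions = if (length(mentions)) do.call(rbind, mentions) else NULL
  )
}

#' Restrict KERs to those connecting key events at given levels
#'
#' Keeps the key-event relationships whose upstream and downstream key
#' events both sit at one of the requested biological-organization levels.
#'
#' @param dataset an `aopwiki_dataset`.
#' @param levels levels defining scope (default molecular, cellular, tissue,
#'   organ).
#' @return the restricted KER data frame, in dataset order.
#' @export
restrict_kers_to_levels <- function(dataset, levels = IN_SCOPE_LEVELS) {
  kes <- filter_key_events(dataset, levels)
  keep <- dataset$kers$upstream_ke %in% kes$ke_id &
    dataset$kers$downstream_ke %in% kes$ke_id
  out <- dataset$kers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
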