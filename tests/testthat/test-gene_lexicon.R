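tp53_lexicon <- function() {
  load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:11998", "TP53", name = "tumor protein p53",
            prev = "TRP53", syn = "p53", ensembl = "ENSG00000141510"))))
}

test_that("a lexicon row expands into its surface forms", {
  lex <- tp53_lexicon()
  expect_equal(nrow(lex$entries), 1L)
  expect_setequal(lex$forms$form, c("TP53", "tumor protein p53", "TRP53", "p53"))
  expect_equal(sum(lex$forms$form_class == "approved_symbol"), 1L)
  expect_equal(nrow(lex$ambiguity), 0L)
})

test_that("forms shared between genes land in the ambiguity index", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "CDKN1A", syn = "p21"),
    lex_row("HGNC:2", "TCEAL1", syn = "p21"))))
  expect_equal(lex$ambiguity$form, "p21")
  expect_setequal(strsplit(lex$ambiguity$gene_ids, ",")[[1]], c("HGNC:1", "HGNC:2"))
})

test_that("defective lexicons are rejected with the reason", {
  expect_error(load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "A1BG"), lex_row("HGNC:1", "A2M")))), "duplicate hgnc_id")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("hgnc_id\tapproved_symbol", "HGNC:1\tA1BG"), bad)
  expect_error(load_gene_lexicon(bad), "missing required column")
  expect_error(load_gene_lexicon(write_lexicon(list(lex_row("HGNC:1", "")))),
               "approved_symbol")
})

test_that("symbols match case-sensitively as whole tokens", {
  lex <- load_gene_lexicon(write_lexicon(list(lex_row("HGNC:1550", "CAT"))))
  expect_equal(nrow(find_gene_mentions("the cat sat on the mat", lex)), 0L)
  m <- find_gene_mentions("reduced CAT activity", lex)
  expect_equal(m$gene_id, "HGNC:1550")
  expect_equal(m$form_class, "approved_symbol")

  lex2 <- tp53_lexicon()
  expect_equal(nrow(find_gene_mentions("STP53X binds DNA", lex2)), 0L)
  m2 <- find_gene_mentions("Activation of TP53 leads to apoptosis", lex2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$matched_form, "TP53")
})

test_that("multi-word names match case-insensitively as token sequences", {
  lex <- tp53_lexicon()
  m <- find_gene_mentions("loss of Tumor Protein P53 function", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$form_class, "approved_name")
  expect_equal(m$gene_id, "HGNC:11998")
})

test_that("adjacent distinct symbols both match", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:2595", "CYP1A1"), lex_row("HGNC:2596", "CYP1A2"))))
  m <- find_gene_mentions("CYP1A1 and CYP1A2 induction", lex)
  expect_equal(nrow(m), 2L)
  expect_setequal(m$gene_id, c("HGNC:2595", "HGNC:2596"))
})

test_that("hyphenated forms are single tokens", {
  lex <- load_gene_lexicon(write_lexicon(list(lex_row("HGNC:6018", "IL6", syn = "IL-6"))))
  m <- find_gene_mentions("elevated IL-6 levels", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$matched_form, "IL-6")
})

test_that("single-character forms are ignored", {
  lex <- load_gene_lexicon(write_lexicon(list(lex_row("HGNC:1", "AB", syn = "X"))))
  expect_equal(nrow(find_gene_mentions("the X factor", lex)), 0L)
})

test_that("longer matches consume their span; no nested matches", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "ZZQ1", name = "protein kinase alpha"),
    lex_row("HGNC:2", "KIN2", syn = "kinase alpha"))))
  m <- find_gene_mentions("activation of protein kinase alpha was seen", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$gene_id, "HGNC:1") # 3-token name wins over the nested 2-token synonym
})

test_that("ambiguous forms emit one flagged mention per claiming gene", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "AAA1", syn = "shared9"),
    lex_row("HGNC:2", "BBB2", syn = "shared9"))))
  m <- find_gene_mentions("levels of shared9 rose", lex)
  expect_equal(nrow(m), 2L)
  expect_true(all(m$ambiguous))
  expect_setequal(m$gene_id, c("HGNC:1", "HGNC:2"))
  expect_equal(length(unique(m$start)), 1L)
})

test_that("mention offsets address the matched text (property over generated cases)", {
  b <- default_bundle()
  lex <- load_gene_lexicon(b$files$lexicon)
  ds <- parse_aopwiki_xml(b$files$xml)
  kes <- filter_key_events(ds)
  checked <- 0L
  for (i in seq_len(nrow(kes))) {
    txt <- kes$description[[i]]
    m <- find_gene_mentions(txt, lex)
    for (j in seq_len(nrow(m))) {
      span <- substr(txt, m$start[[j]] + 1L, m$end[[j]])
      expect_gt(m$end[[j]], m$start[[j]])
      if (m$form_class[[j]] %in% c("approved_symbol", "previous_symbol") ||
          (m$form_class[[j]] == "synonym" && !grepl(" ", m$matched_form[[j]]))) {
        expect_identical(span, m$matched_form[[j]])
      } else {
        expect_identical(tolower(gsub("[^a-z0-9-]+", " ", tolower(span))),
                         tolower(gsub("[^a-z0-9-]+", " ", tolower(m$matched_form[[j]]))))
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("mention finding is deterministic", {
  b <- default_bundle()
  lex <- load_gene_lexicon(b$files$lexicon)
  txt <- parse_aopwiki_xml(b$files$xml)$key_events$description[[1]]
  expect_identical(find_gene_mentions(txt, lex), find_gene_mentions(txt, lex))
})

test_that("adding an unrelated gene never removes existing mentions (monotonicity)", {
  rows <- list(lex_row("HGNC:1", "QWE1", name = "putative effector 1"))
  lex1 <- load_gene_lexicon(write_lexicon(rows))
  lex2 <- load_gene_lexicon(write_lexicon(c(rows, list(lex_row("HGNC:2", "RTY2")))))
  txt <- "signal through QWE1 and the putative effector 1 axis"
  m1 <- find_gene_mentions(txt, lex1)
  m2 <- find_gene_mentions(txt, lex2)
  expect_true(all(paste(m1$gene_id, m1$start) %in% paste(m2$gene_id, m2$start)))
})

test_that("per-KE gene sets aggregate into totals and counts", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "AAA1"), lex_row("HGNC:2", "BBB2"))))
  kes <- data.frame(
    ke_id = c("KE1", "KE2", "KE3"),
    title = "", level = "molecular",
    description = c("role of AAA1 here", "AAA1 with BBB2 together", "nothing at all"),
    stringsAsFactors = FALSE)
  res <- map_genes_in_key_events(kes, lex)
  expect_equal(res$kes_with_genes, 2L)
  expect_setequal(res$genes_total, c("HGNC:1", "HGNC:2"))
  expect_equal(res$per_ke$KE3, character())
  # subset law
  for (s in res$per_ke) expect_true(all(s %in% res$genes_total))
  expect_equal(sum(lengths(res$per_ke) > 0L), res$kes_with_genes)
})

test_that("KER fields are searched independently and unioned", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "AAA1"), lex_row("HGNC:2", "BBB2"))))
  kers <- data.frame(
    ker_id = c("KER1", "KER2"),
    upstream_ke = "KE1", downstream_ke = "KE2",
    description = c("AAA1 triggers the cascade", ""),
    biological_plausibility = c("", ""),
    empirical_support = c("measured BBB2 response", ""),
    stringsAsFactors = FALSE)
  res <- map_genes_in_kers(kers, lex)
  expect_setequal(res$per_ker$KER1, c("HGNC:1", "HGNC:2"))
  expect_equal(res$per_ker$KER2, character())
  expect_equal(res$kers_with_genes, 1L)
  expect_equal(res$mentions$field[res$mentions$gene_id == "HGNC:2"], "empirical_support")
})

test_that("KER restriction keeps only relationships between in-scope KEs", {
  p <- write_dump(
    ke_xml("KE1", "molecular"), ke_xml("KE2", "organ"), ke_xml("KE3", "population"),
    ker_xml("KER1", "KE1", "KE2"), ker_xml("KER2", "KE2", "KE3"))
  ds <- parse_aopwiki_xml(p)
  expect_equal(restrict_kers_to_levels(ds)$ker_id, "KER1")
})
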