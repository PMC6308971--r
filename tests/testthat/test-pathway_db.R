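gpml_text <- function(body = character(),
                      ns = "http://pathvisio.org/GPML/2013a",
                      title = "demo pathway") {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<Pathway xmlns=\"%s\" Name=\"%s\" Version=\"1\">", ns, title),
    body, "</Pathway>")
}

write_gpml <- function(lines, name = "WP901.gpml") {
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

test_that("a membership table loads into namespaced xref sets", {
  db <- load_pathway_table(write_pathway_tsv(list(
    c("WP1", "t", "HGNC_SYMBOL", "TP53"),
    c("WP1", "t", "CHEBI", "CHEBI:16842"))))
  expect_equal(nrow(db$pathways), 1L)
  expect_equal(nrow(db$gene_xrefs), 1L)
  expect_equal(nrow(db$metabolite_xrefs), 1L)
})

test_that("an empty table gives an empty DB where every lookup is empty", {
  db <- load_pathway_table(write_pathway_tsv(list()))
  expect_equal(nrow(db$pathways), 0L)
  lex <- load_gene_lexicon(write_lexicon(list(lex_row("HGNC:1", "TP53"))))
  cov <- genes_pathway_coverage("HGNC:1", db, lex)
  expect_equal(cov$covered, character())
  expect_equal(cov$fraction, 0)
})

test_that("unknown xref namespaces are rejected by name", {
  p <- write_pathway_tsv(list(c("WP1", "t", "ENTREZ", "7157")))
  expect_error(load_pathway_table(p), "ENTREZ")
})

test_that("GPML DataNodes contribute typed xrefs", {
  p <- write_gpml(gpml_text(c(
    "<DataNode TextLabel=\"g1\" Type=\"GeneProduct\"><Xref Database=\"Ensembl\" ID=\"ENSG00000000001\"/></DataNode>",
    "<DataNode TextLabel=\"g2\" Type=\"Protein\"><Xref Database=\"Ensembl\" ID=\"ENSG00000000002\"/></DataNode>",
    "<DataNode TextLabel=\"m\" Type=\"Metabolite\"><Xref Database=\"ChEBI\" ID=\"16842\"/></DataNode>")))
  rec <- parse_gpml(p)
  expect_equal(rec$pathway_id, "WP901")
  expect_equal(nrow(rec$gene_xrefs), 2L)
  expect_true(all(rec$gene_xrefs$namespace == "ENSEMBL"))
  expect_equal(rec$metabolite_xrefs$chebi, "CHEBI:16842") # bare ID normalized
})

test_that("GPML without DataNodes yields empty xref sets", {
  rec <- parse_gpml(write_gpml(gpml_text()))
  expect_equal(nrow(rec$gene_xrefs), 0L)
  expect_equal(nrow(rec$metabolite_xrefs), 0L)
})

test_that("pathway-level ontology terms are captured with their source", {
  p <- write_gpml(gpml_text(c(
    "<Biopax><bp:openControlledVocabulary xmlns:bp=\"http://www.biopax.org/release/biopax-level3.owl#\">",
    "<bp:ID>PW:0000605</bp:ID></bp:openControlledVocabulary></Biopax>")))
  rec <- parse_gpml(p)
  expect_equal(rec$ontology_tags$source, "PW")
  expect_equal(rec$ontology_tags$term_id, "PW:0000605")
})

test_that("non-2013a GPML and nodes without Xref are handled explicitly", {
  old <- write_gpml(gpml_text(ns = "http://genmapp.org/GPML/2008a"))
  expect_error(parse_gpml(old), "2013a")
  p <- write_gpml(gpml_text("<DataNode TextLabel=\"x\" Type=\"GeneProduct\"></DataNode>"))
  expect_warning(rec <- parse_gpml(p), "without Xref")
  expect_equal(nrow(rec$gene_xrefs), 0L)
})

test_that("other xref databases are recorded as OTHER, not dropped", {
  p <- write_gpml(gpml_text(
    "<DataNode TextLabel=\"g\" Type=\"GeneProduct\"><Xref Database=\"Entrez Gene\" ID=\"7157\"/></DataNode>"))
  rec <- parse_gpml(p)
  expect_equal(rec$gene_xrefs$namespace, "OTHER")
})

test_that("the GPML rendering of a bundle equals its membership table", {
  b <- default_bundle()
  db_tsv <- load_pathway_table(b$files$pathways)
  db_gpml <- load_gpml_dir(dirname(b$files$gpml[[1]]))
  key <- function(df) sort(paste(df$pathway_id, df$namespace, df$xref_id))
  expect_equal(key(db_gpml$gene_xrefs), key(db_tsv$gene_xrefs))
  expect_equal(sort(paste(db_gpml$metabolite_xrefs$pathway_id, db_gpml$metabolite_xrefs$chebi)),
               sort(paste(db_tsv$metabolite_xrefs$pathway_id, db_tsv$metabolite_xrefs$chebi)))
  expect_equal(sort(paste(db_gpml$ontology_tags$pathway_id, db_gpml$ontology_tags$source)),
               sort(paste(db_tsv$ontology_tags$pathway_id, db_tsv$ontology_tags$source)))
  expect_setequal(db_gpml$pathways$pathway_id, db_tsv$pathways$pathway_id)
})

test_that("gene coverage bridges namespaces through the lexicon", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:11998", "TP53", ensembl = "ENSG00000141510"),
    lex_row("HGNC:1101", "BRCA2", ensembl = "ENSG00000139618"),
    lex_row("HGNC:3", "XYZ3", ensembl = "ENSG00000000003"))))
  db <- load_pathway_table(write_pathway_tsv(list(
    c("WP1", "t", "HGNC_SYMBOL", "TP53"),
    c("WP2", "t", "ENSEMBL", "ENSG00000139618"),
    c("WP3", "t", "HGNC_ID", "HGNC:3"))))
  cov <- genes_pathway_coverage(c("HGNC:11998", "HGNC:1101", "HGNC:3", "HGNC:9"), db, lex)
  expect_setequal(cov$covered, c("HGNC:11998", "HGNC:1101", "HGNC:3"))
  expect_equal(cov$fraction, 0.75)
  expect_equal(cov$per_gene_pathways$`HGNC:1101`, "WP2")
  expect_equal(cov$namespaces_hit$`HGNC:3`, "HGNC_ID")
})

test_that("coverage of {TP53, BRCA2} against {WP1: TP53} is one half", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("TP53", "TP53"), lex_row("BRCA2", "BRCA2"))))
  db <- load_pathway_table(write_pathway_tsv(list(c("WP1", "t", "HGNC_SYMBOL", "TP53"))))
  cov <- genes_pathway_coverage(c("TP53", "BRCA2"), db, lex)
  expect_equal(cov$covered, "TP53")
  expect_equal(cov$fraction, 0.5)
  empty <- genes_pathway_coverage(character(), db, lex)
  expect_true(is.na(empty$fraction))
})

test_that("coverage is monotone in added pathways and xrefs", {
  lex <- load_gene_lexicon(write_lexicon(list(
    lex_row("HGNC:1", "AAA1"), lex_row("HGNC:2", "BBB2"))))
  db1 <- load_pathway_table(write_pathway_tsv(list(c("WP1", "t", "HGNC_SYMBOL", "AAA1"))))
  db2 <- load_pathway_table(write_pathway_tsv(list(
    c("WP1", "t", "HGNC_SYMBOL", "AAA1"), c("WP2", "t", "HGNC_SYMBOL", "BBB2"))))
  q <- c("HGNC:1", "HGNC:2")
  expect_gte(genes_pathway_coverage(q, db2, lex)$fraction,
             genes_pathway_coverage(q, db1, lex)$fraction)
})

test_that("pathway ontology usage counts each pathway once per source", {
  db <- load_pathway_table(write_pathway_tsv(list(
    c("WP1", "t", "PW", "PW:0000001"),
    c("WP1", "t", "PW", "PW:0000002"),
    c("WP1", "t", "DO", "DOID:1"),
    c("WP2", "t", "HGNC_SYMBOL", "TP53"),
    c("WP3", "t", "", ""))))
  u <- pathway_ontology_usage(db)
  expect_equal(u$pathways_total, 3L)
  expect_equal(u$with_pw, 1L)
  expect_equal(u$with_do, 1L)
  expect_equal(u$with_cl, 0L)
  empty <- pathway_ontology_usage(load_pathway_table(write_pathway_tsv(list())))
  expect_equal(unlist(empty), c(pathways_total = 0L, with_pw = 0L, with_cl = 0L, with_do = 0L))
})

test_that("SPARQL membership queries are deterministic and well-formed", {
  ids <- c("TP53", "HGNC:5", "ENSG00000000001")
  q1 <- build_sparql_membership_query(ids, "gene")
  q2 <- build_sparql_membership_query(rev(ids), "gene")
  expect_identical(q1, q2) # sorted VALUES clause
  expect_match(q1, "SELECT DISTINCT \\?pathway")
  expect_match(q1, "hgnc.symbol/TP53", fixed = TRUE)
  qm <- build_sparql_membership_query("CHEBI:16842", "metabolite")
  expect_match(qm, "chebi/CHEBI:16842", fixed = TRUE)
  expect_match(qm, "wp:Pathway", fixed = TRUE)
  expect_error(build_sparql_membership_query(character(), "gene"), "non-empty")
})
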