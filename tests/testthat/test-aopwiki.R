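test_that("a small dump parses into the expected entity counts", {
  p <- write_dump(
    ke_xml("KE1", "molecular"), ke_xml("KE2", "cellular"), ke_xml("KE3", "individual"),
    ker_xml("KER1", "KE1", "KE2"), ker_xml("KER2", "KE2", "KE3"),
    stressor_xml("ST1", chemicals = list(list(name = "formaldehyde", cas = "50-00-0"))))
  ds <- parse_aopwiki_xml(p)
  expect_s3_class(ds, "aopwiki_dataset")
  expect_equal(nrow(ds$key_events), 3L)
  expect_equal(nrow(ds$kers), 2L)
  expect_equal(nrow(ds$stressors), 1L)
  expect_equal(nrow(ds$unresolved_refs), 0L)
  expect_equal(ds$key_events$ke_id, c("KE1", "KE2", "KE3")) # order preserved
})

test_that("a minimal dump with zero entities yields empty collections", {
  ds <- parse_aopwiki_xml(write_dump())
  expect_equal(nrow(ds$key_events), 0L)
  expect_equal(nrow(ds$kers), 0L)
  expect_equal(nrow(ds$stressors), 0L)
  expect_equal(nrow(ds$annotations), 0L)
})

test_that("markup is stripped and whitespace normalized in descriptions", {
  p <- write_dump(ke_xml("KE1", "molecular",
    description = "<p>Activation  of &lt;b&gt;TP53&lt;/b&gt; leads\n  to   apoptosis</p>"))
  ds <- parse_aopwiki_xml(p)
  expect_equal(ds$key_events$description, "Activation of TP53 leads to apoptosis")
})

test_that("levels map case-insensitively, with absent or unknown mapped to unspecified", {
  p <- write_dump(ke_xml("KE1", "Molecular"), ke_xml("KE2", NA),
                  ke_xml("KE3", "CELLULAR"))
  ds <- parse_aopwiki_xml(p)
  expect_equal(ds$key_events$level, c("molecular", "unspecified", "cellular"))

  p2 <- write_dump(ke_xml("KE1", "galactic"))
  expect_warning(ds2 <- parse_aopwiki_xml(p2), "unknown biological-organization level")
  expect_equal(ds2$key_events$level, "unspecified")

  p3 <- write_dump(ke_xml("KE1", "molecular", description = NA))
  expect_identical(parse_aopwiki_xml(p3)$key_events$description, "")
})

test_that("structural errors are reported with their cause", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<data><unclosed>", bad)
  expect_error(parse_aopwiki_xml(bad), "malformed XML")

  p <- write_dump(ke_xml("KE1"), ns = "http://example.org/other-schema")
  expect_error(parse_aopwiki_xml(p), "other-schema")

  p2 <- write_dump("<key-event><title>t</title></key-event>")
  expect_error(parse_aopwiki_xml(p2), "key-event.*id")

  p3 <- write_dump(ke_xml("KE1"), ke_xml("KE1"))
  expect_error(parse_aopwiki_xml(p3), "duplicate key-event")
})

test_that("unresolved KER endpoints are recorded, never dropped", {
  p <- write_dump(ke_xml("KE1"), ker_xml("KER1", "KE1", "KE99"))
  ds <- parse_aopwiki_xml(p)
  expect_equal(nrow(ds$kers), 1L)
  expect_equal(ds$unresolved_refs$ker_id, "KER1")
  expect_equal(ds$unresolved_refs$ke_id, "KE99")
  expect_equal(ds$unresolved_refs$role, "downstream")
})

test_that("gzip-compressed dumps are sniffed and parsed", {
  p <- write_dump(ke_xml("KE1", "molecular"))
  gz <- tempfile(fileext = ".xml.gz")
  con <- gzfile(gz, "wb")
  writeLines(readLines(p), con)
  close(con)
  ds <- parse_aopwiki_xml(gz)
  expect_equal(ds$key_events$ke_id, "KE1")
})

test_that("parsing is deterministic", {
  b <- default_bundle()
  d1 <- parse_aopwiki_xml(b$files$xml)
  d2 <- parse_aopwiki_xml(b$files$xml)
  expect_identical(d1, d2)
})

test_that("filter_key_events selects by level and rejects bad level sets", {
  p <- write_dump(ke_xml("KE1", "molecular"), ke_xml("KE2", "individual"))
  ds <- parse_aopwiki_xml(p)
  expect_equal(filter_key_events(ds)$ke_id, "KE1")
  all6 <- c("molecular", "cellular", "tissue", "organ", "individual", "population")
  expect_equal(filter_key_events(ds, all6), ds$key_events)
  expect_error(filter_key_events(ds, character()), "non-empty")
  expect_error(filter_key_events(ds, "cosmic"), "unknown level")
})

test_that("extract_chemicals deduplicates by name and CAS", {
  p <- write_dump(
    stressor_xml("ST1", chemicals = list(list(name = "formaldehyde", cas = "50-00-0"))),
    stressor_xml("ST2", chemicals = list(list(name = "formaldehyde", cas = " 50-00-0 "))),
    stressor_xml("ST3", chemicals = list(list(name = "mystery compound", cas = ""))),
    stressor_xml("ST4"))
  chem <- extract_chemicals(parse_aopwiki_xml(p))
  expect_equal(chem$n_stressors, 4L)
  expect_equal(chem$n_unique_chemicals, 2L)
  expect_equal(chem$n_unique_cas, 1L) # CAS trimmed at parse time, empty excluded
  expect_equal(nrow(chem$chemicals), 4L) # no-CAS records retained
})

test_that("ontology usage counts annotated and unannotated KEs per component", {
  p <- write_dump(
    ke_xml("KE1", "molecular",
           annotations = c(ann_xml("biological_process", "GO:0006915"),
                           ann_xml("biological_process", "GO:0008152"),
                           ann_xml("biological_object", "PR:000001111"))),
    ke_xml("KE2", "molecular"))
  tab <- ontology_usage_summary(parse_aopwiki_xml(p), "molecular")
  pick <- function(comp, src) tab$n_kes[tab$component == comp & tab$source == src]
  expect_equal(pick("biological_process", "GO"), 1L) # KE counted once despite 2 GO terms
  expect_equal(pick("biological_process", "unannotated"), 1L)
  expect_equal(pick("biological_object", "PR"), 1L)
  expect_equal(pick("biological_object", "unannotated"), 1L)
  expect_equal(pick("cell_term", "unannotated"), 2L)
})

test_that("a KE with two sources for one component is counted once per source", {
  p <- write_dump(
    ke_xml("KE1", "cellular",
           annotations = c(ann_xml("cell_term", "CL:0000066"),
                           ann_xml("cell_term", "WIKI:12345"))))
  tab <- ontology_usage_summary(parse_aopwiki_xml(p), "cellular")
  expect_equal(tab$n_kes[tab$component == "cell_term" & tab$source == "CL"], 1L)
  expect_equal(tab$n_kes[tab$component == "cell_term" & tab$source == "WIKI"], 1L)
  expect_equal(tab$n_kes[tab$component == "cell_term" & tab$source == "unannotated"], 0L)
})

test_that("ontology usage on a generated bundle matches the manifest", {
  b <- default_bundle()
  ds <- parse_aopwiki_xml(b$files$xml)
  tab <- ontology_usage_summary(ds)
  man <- b$manifest$annotations
  kes <- filter_key_events(ds)
  for (lv in unique(kes$level)) {
    for (comp in unique(man$component)) {
      sub <- man[man$component == comp &
                   man$ke_id %in% kes$ke_id[kes$level == lv], , drop = FALSE]
      for (src in unique(sub$source)) {
        expect_equal(tab$n_kes[tab$level == lv & tab$component == comp & tab$source == src],
                     length(unique(sub$ke_id[sub$source == src])))
      }
      expect_equal(tab$n_kes[tab$level == lv & tab$component == comp &
                               tab$source == "unannotated"],
                   sum(kes$level == lv) - length(unique(sub$ke_id)))
    }
  }
  # per (level, component): unannotated + annotated-per-source >= KEs at level
  for (lv in unique(tab$level)) {
    n_lv <- sum(kes$level == lv)
    for (comp in unique(tab$component)) {
      expect_gte(sum(tab$n_kes[tab$level == lv & tab$component == comp]), n_lv)
    }
  }
})

test_that("ontology sources derive from term prefixes, unknown prefixes kept as OTHER", {
  p <- write_dump(ke_xml("KE1", "molecular",
                         annotations = c(ann_xml("biological_object", "CHEBI:16842"),
                                         ann_xml("biological_object", "XYZZY:1"),
                                         ann_xml("organ_term", "UBERON:0002107"))))
  ds <- parse_aopwiki_xml(p)
  expect_setequal(ds$annotations$source, c("CHEBI", "OTHER", "UBERON"))
})
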