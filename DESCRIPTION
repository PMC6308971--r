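Package: aoplink
Title: Linking Adverse Outcome Pathway Knowledge to Molecular Pathway
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit and link the AOP-Wiki knowledge base of adverse
    outcome pathways (AOPs) with molecular pathway databases in the
    WikiPathways mould. Parses AOP-Wiki quarterly XML dumps into a typed
    dataset of key events, key event relationships and chemical stressors;
    audits ontology annotation usage; validates CAS registry numbers and maps
    them to ChEBI identifiers through a mapping table (hard linkage);
    recognises human gene mentions in key-event free text with an HGNC-style
    dictionary (soft linkage); resolves gene and metabolite pathway
    membership from GPML files, flat tables or SPARQL; and assembles the
    results into a machine-readable coverage report. Ships a deterministic
    synthetic-fixture generator with a ground-truth manifest so every stage
    of the pipeline has an exact oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    digest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
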