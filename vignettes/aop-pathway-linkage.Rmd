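---
title: "Linking an AOP knowledge base to molecular pathways: methods and design"
author: "aoplink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking an AOP knowledge base to molecular pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoplink)
```

## The problem

Adverse outcome pathways (AOPs) organise toxicological knowledge as chains
of key events (KEs) — from a molecular initiating event through cellular,
tissue and organ responses to an adverse outcome — connected by key event
relationships (KERs). The AOP-Wiki publishes this knowledge as quarterly
XML dumps. Molecular pathway databases such as WikiPathways hold the
gene- and metabolite-level mechanisms that omics experiments measure, as
GPML diagrams with RDF/SPARQL access. The two resources barely share formal
identifiers, so the question "how much of the AOP knowledge base can be
connected to pathway content?" has to be answered by a linkage analysis:

1. **Ontology audit.** Which controlled vocabularies annotate KEs, and do
   they overlap with the three ontologies pathways use (Pathway Ontology,
   Cell Ontology, Disease Ontology)? In practice they barely do, which is
   why the linkage below goes through identifiers and text instead.
2. **Hard linkage.** Stressor chemicals carry CAS registry numbers; these
   are mapped to ChEBI identifiers through a mapping table and intersected
   with pathway metabolite content.
3. **Soft linkage.** KE and KER free text is scanned for human gene names
   with an HGNC-derived dictionary; recognised genes are then looked up in
   pathway gene content.
4. **Coverage report.** All counts and percentages are assembled into one
   machine-readable object.

The package implements each stage behind a small functional surface and
ships a synthetic-data generator whose ground-truth manifest provides an
exact oracle for the whole pipeline.

## Parsing and its conventions

`parse_aopwiki_xml()` targets the AOP-Wiki 1.0 dump dialect. The namespace
URI is read from the document root rather than hard-coded, so quarterly
dumps of different dates parse alike; a root namespace that does not look
like an AOP dump namespace is an error naming the URI found. Three
normalisations happen at parse time, because every downstream stage depends
on them:

- **Markup stripping.** Description fields may contain embedded HTML or
  escaped markup. Tags are removed, common entities decoded, and whitespace
  runs collapsed to single spaces. This normalized text is the only
  substrate the gene matcher ever sees, so the tokenizer does not need to
  reason about markup.
- **Levels.** Biological-organization levels are matched
  case-insensitively against
  `molecular, cellular, tissue, organ, individual, population`; an absent
  or unrecognised level maps to `unspecified` (with a warning for
  unrecognised strings). The linkage analysis operates on the four levels
  up to organ; KEs at individual/population level rarely describe molecular
  biology.
- **CAS normalization.** Whitespace is trimmed and the hyphenated form
  kept verbatim, so deduplication ("205 unique CAS numbers") is exact
  string deduplication.

KER endpoints that do not resolve to a KE in the dump are collected in an
`unresolved_refs` table rather than dropped: a dangling reference is a data
defect worth surfacing, not something a parser should silently repair.

**KER scope.** The in-scope KER set is defined as relationships whose
upstream *and* downstream KEs are both at in-scope levels. "KERs that
connect the in-scope KEs" could also be read as *either* endpoint; the
conjunctive reading was chosen because a KER reaching into
individual/population territory is not a link between two
molecular-pathway-describable events. This is a one-line change in
`restrict_kers_to_levels()` if a user needs the other convention.

## CAS validation and chemical mapping

A CAS number is `2-7 digits "-" 2 digits "-" 1 check digit`, and the check
digit is \((\sum_i i \cdot d_i) \bmod 10\) with digits numbered
right-to-left excluding the check digit. `validate_cas()` returns one of
`valid` / `bad_checksum` / `malformed` rather than a logical, because the
pipeline deliberately does **not** filter on the checksum: a mistyped but
resolvable CAS still deserves a mapping attempt, so bad-checksum numbers
are looked up with a warning. Only syntactically malformed strings are
excluded from mapping-table keys.

Mapping is a table join, not a live service call: any two-column TSV
(`cas`, `chebi`) works, so BridgeDb exports, Wikidata extracts and test
fixtures are interchangeable, and the suite runs hermetically. Counts are
over unique CAS numbers and unique ChEBI identifiers, never stressor
multiplicity — that is the arithmetic that makes "194 of 205 CAS mapped to
298 ChEBI IDs" style statements meaningful.

The chemical-coverage fraction is reported against three denominators
(unique ChEBI IDs, unique CAS numbers, unique chemicals) in the report's
`raw` block. The three readings give genuinely different numbers and the
source material for this kind of analysis is often ambiguous about which is
meant, so the report exposes all of them and chooses none.

## Dictionary-based gene recognition

The matcher is deliberately simple — a deterministic dictionary scanner,
not statistical NER — because reproducibility and auditability matter more
here than recall on creative prose. Its rules, all of which are visible in
test cases:

- **Tokens** are maximal runs of letters, digits and hyphens. The hyphen is
  a word character so "IL-6"-style symbols stay single tokens.
- **Case policy.** Symbol-class forms (approved symbols, previous symbols,
  single-token synonyms) match case-sensitively as whole tokens; approved
  names and multi-word synonyms match case-insensitively as whole-token
  sequences. The case-sensitive symbol rule suppresses the classic
  false-positive family (gene symbols CAT, SET, MET as lowercase English
  words) at the cost of missing lowercased symbol mentions; multi-word
  names carry enough context to be safe case-insensitively. Approved names
  follow the name rule even when they happen to be one token long.
- **Minimum form length 2**; single-character forms are ignored
  (alphabet-letter false positives).
- **Overlap resolution** is longest-match-first, ties broken by leftmost
  start, then by form-class priority (approved symbol > previous symbol >
  synonym > approved name). A matched span is consumed, so no nested
  matches: "protein kinase alpha" beats an embedded "kinase alpha".
- **Ambiguity.** A surface form claimed by several genes emits one mention
  per claiming gene, flagged `ambiguous`; no disambiguation is attempted,
  and gene counting is by unique gene identifier, not mention count.

For KERs, the three text fields (description, biological plausibility,
empirical support) are searched independently and unioned per KER.

Pathway coverage of recognised genes bridges namespaces through the
lexicon itself: a gene is covered if its HGNC ID, approved symbol or
Ensembl ID occurs among any pathway's gene xrefs. Using the lexicon as the
single identifier-bridging source keeps the analysis offline-testable; the
report records which namespace produced each hit.

## Pathway membership

`load_pathway_table()` reads a flat `pathway_id / title / xref_namespace /
xref_id` table — the hermetic local stand-in for a SPARQL endpoint.
`parse_gpml()`/`load_gpml_dir()` accept GPML 2013a (the WikiPathways
exchange dialect; other namespace versions are rejected explicitly, since
silently misreading an older diagram is worse than refusing it). Gene xrefs
from other databases (e.g. Entrez) are recorded under `OTHER` rather than
dropped, so the membership view stays auditable.

`build_sparql_membership_query()` emits a SPARQL SELECT over the
WikiPathways RDF vocabulary with a sorted `VALUES` clause, so the same
identifier set always produces the byte-identical query. Remote execution
(`query_sparql_endpoint()`) exists but is never exercised by the pipeline
or the tests; the test suite instead runs the query against the synthetic
bundle's Turtle rendering in an in-process triple store and checks set
equality with table lookup.

## The coverage report

`coverage_report` stores **counts only**. Integer percentages are
recomputed at serialization time as `round_half_up(100 * covered /
identified)` and are `null` when the denominator is zero. Half-up rounding
(rather than R's default half-to-even) is used because it matches the
convention of the descriptive statistics this report mirrors: 296/417
prints as 71, 48/298 as 16. Raw fractions are always retained in the JSON
`raw` block, and the JSON shape is documented by the schema shipped at
`inst/schema/coverage_report.schema.json` (the reader/writer enforce the
same required-key and type constraints directly, as no JSON-Schema
validator is among the package's dependencies).

## The synthetic generator and what passing tests mean

`generate_bundle()` writes a complete input bundle — XML dump, lexicon,
CAS→ChEBI table, pathway TSV, per-pathway GPML, Turtle rendering — plus a
`manifest.json` of everything that was planted. Design points:

- **Determinism.** Same seed and config give byte-identical files. All
  randomness flows from the single seed; file writing uses fixed ordering
  and LF endings.
- **Certified collision-freedom.** Decoy text comes from a fixed embedded
  sentence pool whose vocabulary is disjoint from the name vocabulary used
  to build surface forms; at generation time an independent regex-based
  scanner (boundary-guarded patterns, sharing no code with the tokenizing
  matcher) verifies that each assembled description contains exactly its
  planted genes and that decoys contain none. This is what makes
  "precision = recall = 1" a meaningful oracle rather than a tautology.
- **Exact coverage targets.** `gene_coverage_target` (default 0.70) and
  `metabolite_coverage_target` (default 0.16) place
  `round_half_up(target * n)` of the planted genes / mapped ChEBI IDs into
  pathways, sampled over the union of KE and KER genes; per-subset
  percentages therefore fluctuate around the target while the union-level
  fraction is exact. Unattainable targets (positive target, zero pathways)
  error before anything is written.
- **CAS realism.** Valid CAS numbers are synthesized digit-wise with the
  checksum formula; invalid ones get a deliberately off check digit; a
  configurable fraction appears in the mapping table, and the table also
  carries a few background rows for CAS absent from the dump.
- **Planting discipline.** Genes are drawn from a shuffled global queue,
  without replacement per KE, so planted genes stay distinct until the
  lexicon pool is exhausted and unique-gene totals are exactly
  predictable.

Default configuration (the package's desk-scale study conditions): 38 KEs
across all six levels (12 molecular, 10 cellular, 5 tissue, 5 organ, 4
individual, 2 population), 20 KERs, 0–3 genes per in-scope KE from a
60-gene lexicon, 15 stressors with 90% checksum-valid and 95% mappable CAS,
up to 2 ChEBI per CAS, and 12 pathways. These sizes keep a full
oracle-equivalence sweep (20 random configurations) around a minute while
still exercising every code path: mixed-case levels, markup-wrapped
descriptions, out-of-scope KEs and KERs, chemicals without CAS, shared
chemicals, multi-namespace gene xrefs.

`expected_report()` recomputes every report field from the manifest by
plain set arithmetic — no parsing, no tokenization, no joins — and the
central test asserts `build_coverage_report(bundle) ==
expected_report(manifest)` exactly, across randomized configurations.

What the fixtures do **not** emulate: real biological prose (decoys are a
small fixed pool, so the matcher's false-positive behaviour on genuine
English text is only probed by the case-policy tests, not measured at
scale); the full breadth of the AOP-Wiki schema (only elements the parser
consumes are generated); species ambiguity (the lexicon is human-only, as
is the analysis); and the scale of the real resources (hundreds of KEs,
tens of thousands of pathway xrefs). Passing the oracle tests shows the
pipeline's internal consistency and its exactness on known ground truth —
it does not certify recall on real curator-written text, where lowercased
symbol mentions and creative naming will lose matches by design.

## Degenerate inputs and numerical choices

Empty inputs are legal everywhere: an empty dump yields an all-zero report
with `null` percentages; lookups of absent CAS keys or unknown gene
identifiers return empty sets, never errors. Ties in the matcher are
resolved by the documented priority order, so outputs are deterministic and
byte-stable. All percentages in user-facing output are integers by half-up
rounding; fractions are never stored pre-rounded.

## Limitations

- The external reproduction of published headline numbers requires the
  archived snapshots of the real resources (a pinned AOP-Wiki dump, a
  pinned mapping dataset, a pinned pathway RDF snapshot, and an HGNC table
  whose exact release matters); the package provides the CLI to run that
  analysis when those files are local, but its tests are hermetic and make
  no claims about live data.
- Dictionary NER without disambiguation over-counts genuinely ambiguous
  symbols (each claiming gene is counted, flagged); statistical NER is out
  of scope by design.
- The GPML reader extracts membership and ontology tags only; layout,
  interactions and groups are ignored.
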