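{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "AOP-pathway coverage report",
  "type": "object",
  "required": [
    "stressors", "chemicals", "cas_numbers", "cas_mapped", "chebi_ids",
    "chebi_in_pathways", "chem_pathways_hit", "kes_total", "kes_with_genes",
    "genes_in_kes", "genes_in_kes_covered", "pct_ke_genes_covered",
    "kers_total", "genes_in_kers", "genes_in_kers_covered",
    "pct_ker_genes_covered", "raw", "provenance"
  ],
  "properties": {
    "stressors": { "type": "integer", "minimum": 0 },
    "chemicals": { "type": "integer", "minimum": 0 },
    "cas_numbers": { "type": "integer", "minimum": 0 },
    "cas_mapped": { "type": "integer", "minimum": 0 },
    "chebi_ids": { "type": "integer", "minimum": 0 },
    "chebi_in_pathways": { "type": "integer", "minimum": 0 },
    "chem_pathways_hit": { "type": "integer", "minimum": 0 },
    "kes_total": { "type": "integer", "minimum": 0 },
    "kes_with_genes": { "type": "integer", "minimum": 0 },
    "genes_in_kes": { "type": "integer", "minimum": 0 },
    "genes_in_kes_covered": { "type": "integer", "minimum": 0 },
    "pct_ke_genes_covered": { "type": ["integer", "null"], "minimum": 0, "maximum": 100 },
    "kers_total": { "type": "integer", "minimum": 0 },
    "genes_in_kers": { "type": "integer", "minimum": 0 },
    "genes_in_kers_covered": { "type": "integer", "minimum": 0 },
    "pct_ker_genes_covered": { "type": ["integer", "null"], "minimum": 0, "maximum": 100 },
    "raw": {
      "type": "object",
      "properties": {
        "ke_gene_coverage": { "type": ["number", "null"] },
        "ker_gene_coverage": { "type": ["number", "null"] },
        "cas_mapped_fraction": { "type": ["number", "null"] },
        "chem_coverage_of_chebi": { "type": ["number", "null"] },
        "chem_coverage_of_cas": { "type": ["number", "null"] },
        "chem_coverage_of_chemicals": { "type": ["number", "null"] }
      }
    },
    "provenance": {
      "type": "object",
      "properties": {
        "tool": { "type": "string" },
        "inputs": { "type": "object" },
        "timestamp": { "type": "string" }
      }
    }
  }
}
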