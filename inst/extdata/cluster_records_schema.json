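{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rinpep cluster record set",
  "description": "Array of biosynthetic gene cluster (BGC) prediction records. Each record carries one cluster's per-module monomer calls from the three adenylation-domain specificity predictors reported by antiSMASH v3-era output, plus the most-similar-known-cluster annotation. Populate it from antiSMASH exports with one record per NRPS / hybrid cluster; an absent predictor call is an explicit null, never an empty string.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["organism", "cluster_index", "cluster_type", "modules"],
    "properties": {
      "organism": {"type": "string"},
      "genome_accession": {"type": "string"},
      "cluster_index": {"type": "integer", "minimum": 1},
      "cluster_type": {"type": "string", "examples": ["NRPS", "NRPS-T1PKS"]},
      "modules": {
        "type": "array",
        "description": "Ordered biosynthetic modules; may be empty for draft genomes with no prediction (the record is then retained but contributes no POPs).",
        "items": {
          "type": "object",
          "required": ["NRPSpredictor2", "Stachelhaus", "Minowa"],
          "properties": {
            "NRPSpredictor2": {"type": ["string", "null"]},
            "Stachelhaus": {"type": ["string", "null"]},
            "Minowa": {"type": ["string", "null"]}
          },
          "additionalProperties": false
        }
      },
      "known_match": {
        "type": ["object", "null"],
        "required": ["compound_name", "identity_percent"],
        "properties": {
          "compound_name": {"type": "string"},
          "mibig_id": {"type": "string", "description": "MIBiG accession, optionally with antiSMASH's opaque _c suffix, e.g. BGC0000964_c1"},
          "identity_percent": {"type": "number", "minimum": 0, "maximum": 100,
            "description": "Percent of genes showing homology to the known cluster, carried verbatim from antiSMASH"}
        }
      }
    }
  }
}
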