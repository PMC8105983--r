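{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "qsmine run summary",
  "type": "object",
  "required": ["tool", "version", "assembly", "counts", "config"],
  "properties": {
    "tool": { "type": "string" },
    "version": { "type": "string" },
    "assembly": {
      "type": "object",
      "required": ["total_length", "n_contigs", "gc_percent", "n50"],
      "properties": {
        "total_length": { "type": "integer" },
        "n_contigs": { "type": "integer" },
        "gc_percent": { "type": "number" },
        "n50": { "type": "integer" }
      }
    },
    "counts": {
      "type": "object",
      "required": ["n_genes", "n_candidates", "n_luxi", "n_luxr",
                   "n_pairs", "n_solos"],
      "properties": {
        "n_genes": { "type": "integer" },
        "n_candidates": { "type": "integer" },
        "n_luxi": { "type": "integer" },
        "n_luxr": { "type": "integer" },
        "n_pairs": { "type": "integer" },
        "n_solos": { "type": "integer" }
      }
    },
    "luxr_classifications": { "type": "object" },
    "config": {
      "type": "object",
      "required": ["bits_threshold", "window_size", "min_aa", "seed"],
      "properties": {
        "bits_threshold": { "type": "number" },
        "window_size": { "type": "integer" },
        "min_aa": { "type": "integer" },
        "seed": { "type": "integer" }
      }
    }
  }
}
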