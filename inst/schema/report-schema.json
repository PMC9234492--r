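{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cgpfield pipeline report",
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "config_hash"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "config_hash": {"type": "string"}
      }
    },
    "trial": {
      "type": "object",
      "required": ["n_records", "event_means"]
    },
    "segregation": {"type": "array"},
    "quantification": {"type": "array"},
    "extraction": {"type": "array"},
    "tea": {
      "type": "object",
      "required": ["scenario_table", "monte_carlo", "fine_chemical"],
      "properties": {
        "monte_carlo": {
          "type": "object",
          "required": ["n_reps", "E", "R"]
        }
      }
    },
    "conjoint": {
      "type": "object",
      "required": ["gm_summary"]
    }
  }
}
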