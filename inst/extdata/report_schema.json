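{
  "title": "microstab run_report",
  "description": "Structural schema mirrored by validate_report(); every pipeline run is checked against it.",
  "type": "object",
  "required": ["provenance", "consortia", "endpoints", "correlations_replicate",
               "correlations_consortium", "cmd_cubic", "variance_curves"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "package_version", "r_version", "seed",
                   "settings", "config_checksum"]
    },
    "consortia": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["consortium", "level", "richness", "cmd", "mean_overlap",
                     "redundancy", "v_t", "stability_mean_of_reciprocal",
                     "stability_reciprocal_of_mean"]
      }
    },
    "endpoints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["microcosm_id", "consortium", "richness", "cmd",
                     "etsa", "doc", "v_t", "stability"]
      }
    },
    "correlations_replicate": {
      "type": "array", "minItems": 6, "maxItems": 6,
      "items": {
        "type": "object",
        "required": ["response", "predictor", "r", "p", "n"]
      }
    },
    "correlations_consortium": {
      "type": "array", "minItems": 6, "maxItems": 6,
      "items": {
        "type": "object",
        "required": ["response", "predictor", "r", "p", "n"]
      }
    },
    "cmd_cubic": {
      "type": "object",
      "required": ["coefficients", "rss"]
    },
    "variance_curves": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["microcosm_id", "scale_s", "v_t_a"]
      }
    }
  }
}
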