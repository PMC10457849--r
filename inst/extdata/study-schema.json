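{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sedem study file",
  "description": "One powder-characterization study: raw replicate measurements per batch. Units are fixed: grams, mL, mm, micrometres, seconds, percent.",
  "type": "object",
  "required": ["format", "version", "batches"],
  "properties": {
    "format": {"const": "sedem-study"},
    "version": {"type": "integer"},
    "batches": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source_id", "batch_id", "scale", "replicates"],
        "properties": {
          "source_id": {"type": "string"},
          "batch_id": {"type": "string"},
          "scale": {"enum": ["pilot", "industrial"]},
          "replicates": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["density", "cohesion", "repose", "flow",
                           "moisture", "sieve"],
              "properties": {
                "density": {
                  "type": "object",
                  "required": ["sample_mass", "poured_volume",
                               "tapped_volume"],
                  "properties": {
                    "sample_mass": {"type": "number", "exclusiveMinimum": 0},
                    "poured_volume": {"type": "number",
                                      "exclusiveMinimum": 0},
                    "tapped_volume": {"type": "number",
                                      "exclusiveMinimum": 0}
                  }
                },
                "cohesion": {
                  "type": "object",
                  "required": ["hardness_values", "lubricated",
                               "compressible"],
                  "properties": {
                    "hardness_values": {"type": "array",
                                        "items": {"type": "number",
                                                  "minimum": 0}},
                    "lubricated": {"type": "boolean"},
                    "compressible": {"type": "boolean"}
                  }
                },
                "repose": {
                  "type": "object",
                  "required": ["cone_height", "base_radii"],
                  "properties": {
                    "cone_height": {"type": "number", "minimum": 0},
                    "base_radii": {"type": "array", "minItems": 4,
                                   "maxItems": 4,
                                   "items": {"type": "number",
                                             "exclusiveMinimum": 0}}
                  }
                },
                "flow": {
                  "type": "object",
                  "required": ["non_flowing"],
                  "properties": {
                    "seconds_per_100g": {"type": ["number", "null"],
                                         "minimum": 0},
                    "non_flowing": {"type": "boolean"}
                  }
                },
                "moisture": {
                  "type": "object",
                  "required": ["loss_on_drying_pct", "hygroscopicity_pct"],
                  "properties": {
                    "loss_on_drying_pct": {"type": "number", "minimum": 0},
                    "hygroscopicity_pct": {"type": "number", "minimum": 0}
                  }
                },
                "sieve": {
                  "type": "object",
                  "required": ["apertures", "retained_pct", "pan_pct"],
                  "properties": {
                    "apertures": {"type": "array",
                                  "items": {"type": "number"},
                                  "description": "strictly decreasing, um"},
                    "retained_pct": {"type": "array",
                                     "items": {"type": "number",
                                               "minimum": 0,
                                               "maximum": 100}},
                    "pan_pct": {"type": "number", "minimum": 0,
                                "maximum": 100},
                    "fines_direct_pct": {"type": ["number", "null"],
                                         "minimum": 0, "maximum": 100}
                  }
                },
                "psd": {
                  "type": ["object", "null"],
                  "required": ["sizes", "cumulative_pct"],
                  "properties": {
                    "sizes": {"type": "array",
                              "items": {"type": "number"}},
                    "cumulative_pct": {"type": "array",
                                       "items": {"type": "number"}}
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
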