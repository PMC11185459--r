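{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "metaboPost-empcpd-1.0",
  "title": "Empirical-compound document",
  "description": "Map keyed by empcpd_id (plus the reserved key _schema). Each entry is one empirical compound: MS1 member features with ion relations, attached MS2 spectra, and a chainable annotation list.",
  "type": "object",
  "properties": {
    "_schema": { "const": "metaboPost-empcpd-1.0" }
  },
  "additionalProperties": {
    "type": "object",
    "required": ["empcpd_id", "mode", "members", "ms2_spectra", "annotations"],
    "properties": {
      "empcpd_id": { "type": "string" },
      "neutral_mass": { "type": ["number", "null"], "description": "inferred neutral monoisotopic mass, Daltons" },
      "mode": { "enum": ["pos", "neg"] },
      "members": {
        "type": "array", "minItems": 1,
        "items": {
          "type": "object",
          "required": ["feature_id", "mz", "rtime"],
          "properties": {
            "feature_id": { "type": "string" },
            "mz": { "type": "number", "exclusiveMinimum": 0 },
            "rtime": { "type": "number", "minimum": 0, "description": "seconds" },
            "isotope": { "type": ["string", "null"] },
            "adduct": { "type": ["string", "null"] },
            "charge": { "type": ["integer", "null"] },
            "mass_offset": { "type": ["number", "null"], "description": "total ion offset from the neutral mass, Daltons" }
          }
        }
      },
      "ms2_spectra": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["precursor_mz", "peaks", "provenance"],
          "properties": {
            "precursor_mz": { "type": "number", "exclusiveMinimum": 0 },
            "precursor_rtime": { "type": ["number", "null"] },
            "source": { "type": "string" },
            "provenance": { "enum": ["experimental", "reference_public", "reference_authentic"] },
            "compound": { "type": ["string", "null"] },
            "peaks": {
              "type": "array",
              "items": { "type": "array", "minItems": 2, "maxItems": 2, "items": { "type": "number" } }
            }
          }
        }
      },
      "annotations": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["level", "candidate_name", "source"],
          "properties": {
            "level": { "enum": ["1a", "1b", "2", "4"] },
            "candidate_name": { "type": "string" },
            "candidate_id": { "type": ["string", "null"] },
            "score": { "type": ["number", "null"] },
            "source": { "type": "string" },
            "evidence": { "type": "object" }
          }
        }
      }
    }
  }
}
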