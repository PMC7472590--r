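{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "stecg diagnosis report",
  "type": "object",
  "required": ["record_id", "stemi_ratio", "mi_verdict",
               "inversion_verdict", "rv_flag", "parameters", "leads"],
  "properties": {
    "record_id": { "type": "string" },
    "stemi_ratio": {
      "type": ["number", "null"], "minimum": 0, "maximum": 1,
      "description": "flagged beats / evaluable beats, most affected lead"
    },
    "mi_verdict": { "type": ["boolean", "null"] },
    "inversion_verdict": {
      "type": ["string", "null"], "enum": ["non-inversed", "inversed", null]
    },
    "rv_flag": {
      "type": ["boolean", "null"],
      "description": "II & III & avF all MI-positive; null = indeterminate; a positive flag contraindicates nitroglycerin (NTG)"
    },
    "parameters": { "type": "object" },
    "leads": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "lead": { "type": "string" },
          "nBeats": { "type": "integer" },
          "beats": {
            "description": "per-beat 0-based landmark indices (omega_*), amplitudes in ADC counts, baseline, elevation and STEMI flag"
          },
          "stemiRatio": { "type": ["number", "null"] },
          "miVerdict": { "type": ["boolean", "null"] },
          "threshold": { "type": "object" },
          "lfp": { "type": ["object", "null"] },
          "direction": { "type": ["object", "null"] },
          "finalDirection": { "type": ["string", "null"] },
          "preprocess": { "type": "object" }
        }
      }
    }
  }
}
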