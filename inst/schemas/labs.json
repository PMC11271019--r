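{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "labs",
  "description": "Laboratory signal detection: per-parameter spaghetti and shift data, and optionally the eDish hepatotoxicity scatter.",
  "type": "object",
  "required": ["dataset", "parameters"],
  "properties": {
    "dataset": { "type": "string", "description": "Laboratory domain (usually LB)." },
    "parameters": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Test codes to visualize."
    },
    "edish": { "type": "boolean", "description": "Include the eDish data product (default false)." },
    "alt_code": { "type": "string", "description": "Test code for alanine aminotransferase (default ALT)." },
    "bili_code": { "type": "string", "description": "Test code for total bilirubin (default BILI)." },
    "subset_rule": {
      "type": "string",
      "enum": ["all", "abnormal"],
      "description": "Subject subset for spaghetti data: all, or only subjects with at least one abnormal value."
    },
    "date_var": { "type": "string", "description": "Date variable used to derive the study day when absent (default LBDTC)." }
  }
}
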