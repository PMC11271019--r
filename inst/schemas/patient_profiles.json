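{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "patient_profiles",
  "description": "Index chapter linking every rendered patient-profile document.",
  "type": "object",
  "properties": {
    "subjects": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Restrict the index to these subjects (default: all rendered profiles)."
    }
  }
}
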