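{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "disposition",
  "description": "Subject disposition: completed/discontinued counts with a discontinuation-reason listing, and the subjects-by-visit attendance chart.",
  "type": "object",
  "required": ["dataset"],
  "properties": {
    "dataset": { "type": "string", "description": "Disposition domain (usually DS)." },
    "status_var": { "type": "string", "description": "Disposition status variable (default DSDECOD)." },
    "reason_var": { "type": "string", "description": "Discontinuation reason variable (default DSTERM)." },
    "visit_dataset": { "type": "string", "description": "Subject-visit domain for the attendance chart (default SV)." }
  }
}
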