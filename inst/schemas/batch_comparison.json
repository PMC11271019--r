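{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "batch_comparison",
  "description": "Record-level comparison against the previous data batch: additions, removals and changes with per-variable flags.",
  "type": "object",
  "required": ["dataset"],
  "properties": {
    "dataset": { "type": "string", "description": "Domain to compare (usually AE)." },
    "keys": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Record key variables; defaults come from the packaged per-domain key configuration."
    },
    "label_vars": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Extra variables displayed in the diff listing."
    }
  }
}
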