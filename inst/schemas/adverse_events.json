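{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "adverse_events",
  "description": "Treatment-emergent adverse-event incidence table at worst severity, with SOC/PT hierarchy data for treemap and sunburst charts.",
  "type": "object",
  "required": ["dataset"],
  "properties": {
    "dataset": { "type": "string", "description": "Adverse-event domain (usually AE)." },
    "exposure_dataset": { "type": "string", "description": "Exposure domain for the treatment window (default EX)." },
    "teae_only": { "type": "boolean", "description": "Restrict to treatment-emergent events (default true)." },
    "lag_days": { "type": "integer", "description": "Days after last dose still counted on-treatment (default 30)." }
  }
}
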