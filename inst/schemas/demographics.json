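{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "demographics",
  "description": "Baseline summary tables: distinct-subject counts and percentages for categorical variables, descriptive statistics for continuous variables, per treatment arm (or pooled when blinded).",
  "type": "object",
  "required": ["dataset"],
  "properties": {
    "dataset": {
      "type": "string",
      "description": "Domain code of the demographics table (usually DM)."
    },
    "categorical_vars": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Categorical variables to summarize."
    },
    "continuous_vars": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Continuous variables to summarize."
    }
  }
}
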