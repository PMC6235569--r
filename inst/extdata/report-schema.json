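{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "epiosc pipeline report",
  "type": "object",
  "required": ["package_version", "config", "config_hash", "conditions"],
  "properties": {
    "package_version": {"type": "string"},
    "config": {"type": "object"},
    "config_hash": {"type": "string"},
    "conditions": {
      "type": "object",
      "required_each": ["replicates", "model", "sim_file", "sim_reversals_h"]
    },
    "comparisons": {"type": ["object", "null"]}
  }
}
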