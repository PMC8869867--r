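{
  "title": "proteaphagy run report",
  "type": "object",
  "required": ["package", "version", "seed", "config", "stages"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "stages": {"type": "object"}
  }
}
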