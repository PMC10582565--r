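{
  "title": "jmenet pipeline report",
  "required": {
    "seed": "number",
    "config": "object",
    "cohort": "object",
    "network": "object",
    "communities": "object",
    "centrality": "object",
    "configurations": "object",
    "core": "object",
    "core_modes": "object",
    "mean_core_cb": "object",
    "consistency": "object?",
    "timestamp": "string"
  }
}
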