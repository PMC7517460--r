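{
  "type": "gaussian",
  "components": [
    {"weight": 0.5, "mean": 0, "sd": 0.5},
    {"weight": 0.5, "mean": 6, "sd": 0.5}
  ]
}
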