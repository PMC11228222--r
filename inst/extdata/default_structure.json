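{
  "states": ["NEVER", "NONCURRENT", "ECIG_ONLY", "SMOKING"],
  "arrows": {
    "from": ["NEVER", "NEVER", "NONCURRENT", "NONCURRENT", "ECIG_ONLY", "ECIG_ONLY", "SMOKING", "SMOKING"],
    "to": ["ECIG_ONLY", "SMOKING", "ECIG_ONLY", "SMOKING", "NONCURRENT", "SMOKING", "NONCURRENT", "ECIG_ONLY"]
  }
}
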