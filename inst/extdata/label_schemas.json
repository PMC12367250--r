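{
  "version": "1.0",
  "schemas": {
    "abdomen": {
      "label_ids": {
        "VB": 1, "PM": 2, "CM": 3, "sSAT": 4, "dSAT": 5, "IPAT": 6, "RPAT": 7
      },
      "merge_rules": {
        "SAT": ["sSAT", "dSAT"],
        "VAT": ["IPAT", "RPAT"]
      }
    },
    "thigh": {
      "label_ids": {
        "femur": 1, "vessel": 2, "SAT": 3, "muscle": 4
      },
      "merge_rules": {}
    }
  }
}
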