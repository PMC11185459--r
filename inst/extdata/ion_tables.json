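{
  "mode": "pos",
  "isotopes": [
    { "label": "M0", "offset": 0.0 },
    { "label": "13C/3C1", "offset": 1.003355 },
    { "label": "13C/3C2", "offset": 2.006710 }
  ],
  "adducts": [
    { "label": "M+H+", "offset": 1.007276 },
    { "label": "M+NH4+", "offset": 18.033823 },
    { "label": "M+Na+", "offset": 22.989218 }
  ]
}
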