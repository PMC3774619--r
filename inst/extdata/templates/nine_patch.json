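{
  "name": "nine_patch",
  "patches": [
    {"category": "dark",  "vertices": [[0.0000000000000000, 0.0000000000000000], [0.3333333333333333, 0.0000000000000000], [0.3333333333333333, 0.3333333333333333], [0.0000000000000000, 0.3333333333333333]]},
    {"category": "light", "vertices": [[0.3333333333333333, 0.0000000000000000], [0.6666666666666667, 0.0000000000000000], [0.6666666666666667, 0.3333333333333333], [0.3333333333333333, 0.3333333333333333]]},
    {"category": "dark",  "vertices": [[0.6666666666666667, 0.0000000000000000], [1.0000000000000000, 0.0000000000000000], [1.0000000000000000, 0.3333333333333333], [0.6666666666666667, 0.3333333333333333]]},
    {"category": "light", "vertices": [[0.0000000000000000, 0.3333333333333333], [0.3333333333333333, 0.3333333333333333], [0.3333333333333333, 0.6666666666666667], [0.0000000000000000, 0.6666666666666667]]},
    {"category": "dark",  "vertices": [[0.3333333333333333, 0.3333333333333333], [0.6666666666666667, 0.3333333333333333], [0.6666666666666667, 0.6666666666666667], [0.3333333333333333, 0.6666666666666667]]},
    {"category": "light", "vertices": [[0.6666666666666667, 0.3333333333333333], [1.0000000000000000, 0.3333333333333333], [1.0000000000000000, 0.6666666666666667], [0.6666666666666667, 0.6666666666666667]]},
    {"category": "dark",  "vertices": [[0.0000000000000000, 0.6666666666666667], [0.3333333333333333, 0.6666666666666667], [0.3333333333333333, 1.0000000000000000], [0.0000000000000000, 1.0000000000000000]]},
    {"category": "light", "vertices": [[0.3333333333333333, 0.6666666666666667], [0.6666666666666667, 0.6666666666666667], [0.6666666666666667, 1.0000000000000000], [0.3333333333333333, 1.0000000000000000]]},
    {"category": "dark",  "vertices": [[0.6666666666666667, 0.6666666666666667], [1.0000000000000000, 0.6666666666666667], [1.0000000000000000, 1.0000000000000000], [0.6666666666666667, 1.0000000000000000]]}
  ]
}
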