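{
  "events": {
    "A": "breast cancer",
    "notA": "no breast cancer",
    "B": "positive test result",
    "notB": "negative test result"
  },
  "given": {
    "P(A)": 0.02,
    "P(B|A)": 0.8,
    "P(B|notA)": 0.1
  },
  "N": 10000
}
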