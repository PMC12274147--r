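{
  "id": "id",
  "C": ["gender", "race", "age", "income"],
  "L": "l",
  "X": "x",
  "Y": "y",
  "T": 3
}
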