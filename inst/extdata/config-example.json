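{
  "windowBp": 20000,
  "stepBp": 2000,
  "nPerm": 1000,
  "level": 0.95,
  "indexMin": 0.3,
  "depthMin": 7,
  "fpkmMin": 1,
  "lfcMin": 1,
  "qMax": 0.05,
  "seed": 1,
  "sim": {
    "popSize": 200,
    "bulkSize": 30,
    "parentDepthMean": 10,
    "bulkDepthMean": 50,
    "qtlEffect": -15
  }
}
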