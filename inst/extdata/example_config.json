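{
  "recordsPath": "records.csv",
  "treePath": "host_tree.nwk",
  "minRecords": 3,
  "excludedGenera": ["Bos", "Bubalus", "Ovis", "Capra", "Sus", "Equus",
                     "Canis", "Felis", "Oryctolagus", "Cavia", "Gallus"],
  "resolution": 1.0,
  "nRestarts": 20,
  "nNull": 999,
  "nReps": 200,
  "removalPolicy": "random",
  "seed": 1,
  "outputDir": "ticknet_out"
}
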