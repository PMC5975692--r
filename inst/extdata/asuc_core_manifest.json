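{
  "id": "ASUC-CORE",
  "n_reactions": 69,
  "n_metabolites": 64,
  "n_genes": 60,
  "n_exchanges": 15,
  "options": {
    "transporter": "both",
    "me2": "reversible",
    "hydrogenase": false,
    "dmso": false
  }
}
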