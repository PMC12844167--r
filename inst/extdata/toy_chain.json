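{
  "id": "toy_chain",
  "objective": "EX_B",
  "compartments": {"e": "extracellular", "c": "cytosol"},
  "metabolites": [
    {"id": "A_e", "name": "substrate A", "compartment": "e"},
    {"id": "B_c", "name": "product B", "compartment": "c"}
  ],
  "genes": [{"id": "g1", "name": "transporter gene"}],
  "reactions": [
    {"id": "EX_A", "name": "A exchange", "metabolites": {"A_e": -1},
     "lower_bound": -5, "upper_bound": 0, "subsystem": "Exchange"},
    {"id": "AB", "name": "A to B", "metabolites": {"A_e": -1, "B_c": 1},
     "lower_bound": 0, "upper_bound": 100, "gene_reaction_rule": "g1",
     "subsystem": "Central metabolism"},
    {"id": "EX_B", "name": "B export", "metabolites": {"B_c": -1},
     "lower_bound": 0, "upper_bound": 100, "subsystem": "Exchange"}
  ]
}
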