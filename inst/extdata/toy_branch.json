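{
  "metabolites": [
    {
      "id": "A",
      "name": "",
      "compartment": "",
      "boundary_condition": false
    },
    {
      "id": "B",
      "name": "",
      "compartment": "",
      "boundary_condition": false
    },
    {
      "id": "C",
      "name": "",
      "compartment": "",
      "boundary_condition": false
    }
  ],
  "reactions": [
    {
      "id": "E1",
      "name": "",
      "metabolites": {
        "A": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "g_E1",
      "subsystem": ""
    },
    {
      "id": "R1",
      "name": "",
      "metabolites": {
        "A": -1,
        "B": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "g_R1",
      "subsystem": ""
    },
    {
      "id": "R2",
      "name": "",
      "metabolites": {
        "A": -1,
        "C": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "g_R2",
      "subsystem": ""
    },
    {
      "id": "E2",
      "name": "",
      "metabolites": {
        "B": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "g_E2",
      "subsystem": ""
    },
    {
      "id": "E3",
      "name": "",
      "metabolites": {
        "C": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "g_E3",
      "subsystem": ""
    }
  ],
  "genes": [
    {
      "id": "g_E1",
      "name": "g_E1"
    },
    {
      "id": "g_R1",
      "name": "g_R1"
    },
    {
      "id": "g_R2",
      "name": "g_R2"
    },
    {
      "id": "g_E2",
      "name": "g_E2"
    },
    {
      "id": "g_E3",
      "name": "g_E3"
    }
  ],
  "id": "fluxorder_model"
}
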