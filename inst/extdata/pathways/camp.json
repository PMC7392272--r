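{
  "pathway_id": "camp",
  "name": "cAMP signaling pathway",
  "nodes": [
    {"node_id": "nppa", "label": "NPPA", "role": "initiator", "members": ["NPPA"]},
    {"node_id": "adcyap1r1", "label": "ADCYAP1R1", "role": "intermediate", "members": ["ADCYAP1R1"]},
    {"node_id": "gnas", "label": "GNAS", "role": "intermediate", "members": ["GNAS"]},
    {"node_id": "adcy5_6", "label": "ADCY5/6", "role": "intermediate", "members": ["ADCY5", "ADCY6"]},
    {"node_id": "prkca_b_g", "label": "PRKCA/B/G", "role": "intermediate", "members": ["PRKCA", "PRKCB", "PRKCG"]},
    {"node_id": "rapgef3_4", "label": "RAPGEF3/4", "role": "intermediate", "members": ["RAPGEF3", "RAPGEF4"]},
    {"node_id": "rap1a_b", "label": "RAP1A/B", "role": "intermediate", "members": ["RAP1A", "RAP1B"]},
    {"node_id": "map2k1_2", "label": "MAP2K1/2", "role": "intermediate", "members": ["MAP2K1", "MAP2K2"]},
    {"node_id": "mapk1_3", "label": "MAPK1/3", "role": "intermediate", "members": ["MAPK1", "MAPK3"]},
    {"node_id": "jun", "label": "JUN", "role": "effector", "members": ["JUN"]},
    {"node_id": "fos", "label": "FOS", "role": "effector", "members": ["FOS"]},
    {"node_id": "afdn", "label": "AFDN", "role": "effector", "members": ["AFDN"]},
    {"node_id": "vav2", "label": "VAV2", "role": "intermediate", "members": ["VAV2"]},
    {"node_id": "rac1", "label": "RAC1", "role": "intermediate", "members": ["RAC1"]},
    {"node_id": "pak1", "label": "PAK1", "role": "effector", "members": ["PAK1"]},
    {"node_id": "pi3k", "label": "PI3K", "role": "intermediate", "members": ["PIK3CA", "PIK3CB"]},
    {"node_id": "akt1_2_3", "label": "AKT1/2/3", "role": "effector", "members": ["AKT1", "AKT2", "AKT3"]},
    {"node_id": "ppp1c", "label": "PPP1CA/B/C", "role": "intermediate", "members": ["PPP1CA", "PPP1CB", "PPP1CC"]},
    {"node_id": "creb", "label": "CREB", "role": "effector", "members": ["CREB1"],
     "annotation": "downregulated at P28 in MI hearts; down-status is annotated, it never satisfies a chain"}
  ],
  "edges": [
    ["nppa", "adcyap1r1"],
    ["adcyap1r1", "gnas"],
    ["gnas", "adcy5_6"],
    ["adcy5_6", "prkca_b_g"],
    ["adcy5_6", "rapgef3_4"],
    ["rapgef3_4", "rap1a_b"],
    ["rap1a_b", "map2k1_2"],
    ["prkca_b_g", "map2k1_2"],
    ["map2k1_2", "mapk1_3"],
    ["mapk1_3", "jun"],
    ["mapk1_3", "fos"],
    ["rap1a_b", "afdn"],
    ["rap1a_b", "vav2"],
    ["vav2", "rac1"],
    ["rac1", "pak1"],
    ["rap1a_b", "pi3k"],
    ["pi3k", "akt1_2_3"],
    ["prkca_b_g", "ppp1c"],
    ["ppp1c", "creb"]
  ],
  "subpathways": {
    "gpcr_mapk": ["nppa", "adcyap1r1", "gnas", "adcy5_6", "prkca_b_g", "rapgef3_4", "rap1a_b", "map2k1_2", "mapk1_3", "jun", "fos"],
    "rap1_effectors": ["rap1a_b", "afdn", "vav2", "rac1", "pak1", "pi3k", "akt1_2_3"],
    "creb_inhibition": ["prkca_b_g", "ppp1c", "creb"]
  }
}
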