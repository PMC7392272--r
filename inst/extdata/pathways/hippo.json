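{
  "pathway_id": "hippo",
  "name": "Hippo signaling pathway",
  "nodes": [
    {"node_id": "nf2", "label": "NF2 (MERLIN)", "role": "initiator", "members": ["NF2"]},
    {"node_id": "sav1", "label": "SAV1", "role": "intermediate", "members": ["SAV1"]},
    {"node_id": "lats1_2", "label": "LATS1/2", "role": "intermediate", "members": ["LATS1", "LATS2"]},
    {"node_id": "yap1_wwtr1", "label": "YAP1/WWTR1", "role": "effector", "members": ["YAP1", "WWTR1"],
     "annotation": "expression similar in MI and age-matched controls at both collection days"},
    {"node_id": "tgfb", "label": "TGFB", "role": "initiator", "members": ["TGFB1"]},
    {"node_id": "smad2_3", "label": "SMAD2/3", "role": "intermediate", "members": ["SMAD2", "SMAD3"]},
    {"node_id": "fgf1", "label": "FGF1", "role": "effector", "members": ["FGF1"]},
    {"node_id": "itgb2", "label": "ITGB2", "role": "effector", "members": ["ITGB2"]}
  ],
  "edges": [
    ["nf2", "sav1"],
    ["sav1", "lats1_2"],
    ["lats1_2", "yap1_wwtr1"],
    ["tgfb", "smad2_3"],
    ["smad2_3", "fgf1"],
    ["smad2_3", "itgb2"]
  ],
  "subpathways": {
    "core_kinase_cassette": ["nf2", "sav1", "lats1_2", "yap1_wwtr1"],
    "tgfb_smad": ["tgfb", "smad2_3", "fgf1", "itgb2"]
  }
}
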