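{
  "pathway_id": "ras",
  "name": "Ras signaling pathway",
  "nodes": [
    {"node_id": "csf1_csf1r", "label": "CSF1/CSF1R", "role": "initiator", "members": ["CSF1", "CSF1R"]},
    {"node_id": "afdn", "label": "AFDN", "role": "effector", "members": ["AFDN"],
     "annotation": "controls formation of intercellular junctions"},
    {"node_id": "pi3k", "label": "PI3K", "role": "intermediate", "members": ["PIK3CA", "PIK3CB"]},
    {"node_id": "akt1_2_3", "label": "AKT1/2/3", "role": "intermediate", "members": ["AKT1", "AKT2", "AKT3"]},
    {"node_id": "ikbkg", "label": "IKBKG", "role": "intermediate", "members": ["IKBKG"]},
    {"node_id": "nfkb1_rela", "label": "NFKB1/RELA", "role": "effector", "members": ["NFKB1", "RELA"]}
  ],
  "edges": [
    ["csf1_csf1r", "afdn"],
    ["csf1_csf1r", "pi3k"],
    ["pi3k", "akt1_2_3"],
    ["akt1_2_3", "ikbkg"],
    ["ikbkg", "nfkb1_rela"]
  ],
  "subpathways": {
    "junction_formation": ["csf1_csf1r", "afdn"],
    "pi3k_nfkb": ["csf1_csf1r", "pi3k", "akt1_2_3", "ikbkg", "nfkb1_rela"]
  }
}
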