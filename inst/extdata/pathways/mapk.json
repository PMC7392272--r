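{
  "pathway_id": "mapk",
  "name": "MAPK signaling pathway",
  "nodes": [
    {"node_id": "csf1_csf1r", "label": "CSF1/CSF1R", "role": "initiator", "members": ["CSF1", "CSF1R"]},
    {"node_id": "cd14", "label": "CD14", "role": "initiator", "members": ["CD14"]},
    {"node_id": "grb2", "label": "GRB2", "role": "intermediate", "members": ["GRB2"]},
    {"node_id": "sos1_2", "label": "SOS1/2", "role": "intermediate", "members": ["SOS1", "SOS2"]},
    {"node_id": "kras_nras", "label": "KRAS/NRAS", "role": "intermediate", "members": ["KRAS", "NRAS"]},
    {"node_id": "araf_raf1", "label": "ARAF/RAF1", "role": "intermediate", "members": ["ARAF", "RAF1"]},
    {"node_id": "map2k1_2", "label": "MAP2K1/2", "role": "intermediate", "members": ["MAP2K1", "MAP2K2"]},
    {"node_id": "mapk1_3", "label": "MAPK1/3", "role": "intermediate", "members": ["MAPK1", "MAPK3"]},
    {"node_id": "atf4", "label": "ATF4", "role": "effector", "members": ["ATF4"]},
    {"node_id": "elk4", "label": "ELK4", "role": "effector", "members": ["ELK4"]},
    {"node_id": "myc", "label": "MYC", "role": "effector", "members": ["MYC"]},
    {"node_id": "srf", "label": "SRF", "role": "effector", "members": ["SRF"]},
    {"node_id": "fos", "label": "FOS", "role": "effector", "members": ["FOS"]},
    {"node_id": "map3k1", "label": "MAP3K1", "role": "intermediate", "members": ["MAP3K1"]},
    {"node_id": "map2k4", "label": "MAP2K4", "role": "intermediate", "members": ["MAP2K4"]},
    {"node_id": "mapk8_9_10", "label": "MAPK8/9/10", "role": "intermediate", "members": ["MAPK8", "MAPK9", "MAPK10"]},
    {"node_id": "jund", "label": "JUND", "role": "effector", "members": ["JUND"]},
    {"node_id": "tab1_2", "label": "TAB1/2", "role": "intermediate", "members": ["TAB1", "TAB2"]},
    {"node_id": "map3k7", "label": "MAP3K7", "role": "intermediate", "members": ["MAP3K7"]},
    {"node_id": "ikbkg", "label": "IKBKG", "role": "intermediate", "members": ["IKBKG"]},
    {"node_id": "nfkb1_2", "label": "NFKB1/2", "role": "intermediate", "members": ["NFKB1", "NFKB2"]},
    {"node_id": "rela_relb", "label": "RELA/RELB", "role": "effector", "members": ["RELA", "RELB"]}
  ],
  "edges": [
    ["csf1_csf1r", "grb2"],
    ["grb2", "sos1_2"],
    ["sos1_2", "kras_nras"],
    ["kras_nras", "araf_raf1"],
    ["araf_raf1", "map2k1_2"],
    ["map2k1_2", "mapk1_3"],
    ["mapk1_3", "atf4"],
    ["mapk1_3", "elk4"],
    ["mapk1_3", "myc"],
    ["mapk1_3", "srf"],
    ["mapk1_3", "fos"],
    ["kras_nras", "map3k1"],
    ["map3k1", "map2k4"],
    ["map2k4", "mapk8_9_10"],
    ["mapk8_9_10", "fos"],
    ["mapk8_9_10", "jund"],
    ["cd14", "tab1_2"],
    ["tab1_2", "map3k7"],
    ["map3k7", "ikbkg"],
    ["ikbkg", "nfkb1_2"],
    ["nfkb1_2", "rela_relb"]
  ],
  "subpathways": {
    "canonical": ["csf1_csf1r", "grb2", "sos1_2", "kras_nras", "araf_raf1", "map2k1_2", "mapk1_3", "atf4", "elk4", "myc", "srf", "fos"],
    "stress_activated": ["csf1_csf1r", "grb2", "sos1_2", "kras_nras", "map3k1", "map2k4", "mapk8_9_10", "fos", "jund"],
    "nfkb_branch": ["cd14", "tab1_2", "map3k7", "ikbkg", "nfkb1_2", "rela_relb"]
  }
}
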