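{
  "pathway_id": "jak_stat",
  "name": "JAK-STAT signaling pathway",
  "nodes": [
    {"node_id": "csf1_csf1r", "label": "CSF1/CSF1R", "role": "initiator", "members": ["CSF1", "CSF1R"]},
    {"node_id": "jak1_2", "label": "JAK1/2", "role": "intermediate", "members": ["JAK1", "JAK2"]},
    {"node_id": "stat3", "label": "STAT3", "role": "intermediate", "members": ["STAT3"]},
    {"node_id": "pim1", "label": "PIM1", "role": "effector", "members": ["PIM1"]},
    {"node_id": "myc", "label": "MYC", "role": "intermediate", "members": ["MYC"]},
    {"node_id": "ccnd1_2_3", "label": "CCND1/2/3", "role": "effector", "members": ["CCND1", "CCND2", "CCND3"]},
    {"node_id": "ptpn11_grb2", "label": "PTPN11/GRB2", "role": "intermediate", "members": ["PTPN11", "GRB2"]},
    {"node_id": "sos1_2", "label": "SOS1/2", "role": "intermediate", "members": ["SOS1", "SOS2"]},
    {"node_id": "hras", "label": "HRAS", "role": "intermediate", "members": ["HRAS"]},
    {"node_id": "raf1", "label": "RAF1", "role": "effector", "members": ["RAF1"]},
    {"node_id": "pi3k", "label": "PI3K", "role": "intermediate", "members": ["PIK3CA", "PIK3CB"]},
    {"node_id": "akt1_2_3", "label": "AKT1/2/3", "role": "intermediate", "members": ["AKT1", "AKT2", "AKT3"]},
    {"node_id": "mtor", "label": "MTOR", "role": "effector", "members": ["MTOR"]}
  ],
  "edges": [
    ["csf1_csf1r", "jak1_2"],
    ["jak1_2", "stat3"],
    ["stat3", "pim1"],
    ["stat3", "myc"],
    ["myc", "ccnd1_2_3"],
    ["csf1_csf1r", "ptpn11_grb2"],
    ["ptpn11_grb2", "sos1_2"],
    ["sos1_2", "hras"],
    ["hras", "raf1"],
    ["jak1_2", "pi3k"],
    ["pi3k", "akt1_2_3"],
    ["akt1_2_3", "mtor"]
  ],
  "subpathways": {
    "anti_apoptotic": ["csf1_csf1r", "jak1_2", "stat3", "pim1"],
    "cell_cycle": ["csf1_csf1r", "jak1_2", "stat3", "myc", "ccnd1_2_3"],
    "ras_raf": ["csf1_csf1r", "ptpn11_grb2", "sos1_2", "hras", "raf1"],
    "pi3k_mtor": ["csf1_csf1r", "jak1_2", "pi3k", "akt1_2_3", "mtor"]
  }
}
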