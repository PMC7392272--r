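{
  "metadata": {
    "description": "Candidate cell-cycle / cell-fate signaling pathways screened for comprehensive upregulation after neonatal myocardial infarction.",
    "note": "The study's sections disagree on the candidate count (11 vs 20); this catalog follows the enumerated 20-pathway list. Entries without a detailed graph carry no node lists and are reported as not called, never as not upregulated."
  },
  "entries": [
    {"pathway_id": "mapk", "name": "MAPK signaling pathway", "graph_file": "mapk.json"},
    {"pathway_id": "hippo", "name": "Hippo signaling pathway", "graph_file": "hippo.json"},
    {"pathway_id": "ras", "name": "Ras signaling pathway", "graph_file": "ras.json"},
    {"pathway_id": "vegf", "name": "VEGF signaling pathway", "graph_file": null},
    {"pathway_id": "wnt", "name": "Wnt signaling pathway", "graph_file": null},
    {"pathway_id": "rap1", "name": "Rap1 signaling pathway", "graph_file": null},
    {"pathway_id": "hedgehog", "name": "Hedgehog signaling pathway", "graph_file": null},
    {"pathway_id": "jak_stat", "name": "JAK-STAT signaling pathway", "graph_file": "jak_stat.json"},
    {"pathway_id": "camp", "name": "cAMP signaling pathway", "graph_file": "camp.json"},
    {"pathway_id": "erbb", "name": "ErbB signaling pathway", "graph_file": null},
    {"pathway_id": "cgmp_pkg", "name": "cGMP-PKG signaling pathway", "graph_file": null},
    {"pathway_id": "apelin", "name": "Apelin signaling pathway", "graph_file": null},
    {"pathway_id": "nfkb", "name": "NF-kappa B signaling pathway", "graph_file": null},
    {"pathway_id": "tnf", "name": "TNF signaling pathway", "graph_file": null},
    {"pathway_id": "hif1", "name": "HIF-1 signaling pathway", "graph_file": null},
    {"pathway_id": "foxo", "name": "FoxO signaling pathway", "graph_file": null},
    {"pathway_id": "sphingolipid", "name": "Sphingolipid signaling pathway", "graph_file": null},
    {"pathway_id": "phospholipase_d", "name": "Phospholipase D signaling pathway", "graph_file": null},
    {"pathway_id": "mtor", "name": "mTOR signaling pathway", "graph_file": null},
    {"pathway_id": "ampk", "name": "AMPK signaling pathway", "graph_file": null}
  ]
}
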