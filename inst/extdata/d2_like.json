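{
  "name": "dopamine-D2-like",
  "comment": "Target configuration mirroring the dopamine D2 receptor setup: helical spans, per-helix conserved-residue tether counts (mean 7), the 12 +/- 2 A aspartate-to-serine-midpoint anchor window, and the pose acceptance criteria.",
  "spans": [[34, 62], [67, 97], [102, 134], [149, 173], [185, 211], [368, 400], [405, 425]],
  "tether_counts": [3, 10, 6, 5, 10, 11, 4],
  "target": {
    "ser_resids": [193, 197],
    "asp_resid": 114,
    "phe_resids": [389, 390],
    "phe_filter": 390,
    "anchor": {"target": 12, "halfwidth": 2}
  },
  "criteria": {
    "hbond_asp_max": -0.2,
    "hbond_ser_max": -0.2,
    "aromatic_vdw_max": -0.3
  },
  "ligand": "R-NPA"
}
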