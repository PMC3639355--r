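{
  "name": "beta1AR-like",
  "comment": "Target configuration mirroring the turkey beta1 adrenergic receptor test case: helical spans, per-helix tether counts, and the 9.5 +/- 1.5 A anchor window between the TM3 aspartate and TM5 serine Calpha midpoint.",
  "spans": [[40, 68], [75, 103], [110, 142], [155, 177], [205, 233], [286, 314], [322, 343]],
  "tether_counts": [5, 7, 9, 3, 7, 7, 5],
  "target": {
    "ser_resids": [211, 215],
    "asp_resid": 121,
    "phe_resids": [306, 307],
    "phe_filter": 307,
    "anchor": {"target": 9.5, "halfwidth": 1.5}
  },
  "criteria": {
    "hbond_asp_max": -0.2,
    "hbond_ser_max": -0.2,
    "aromatic_vdw_max": -0.3
  },
  "ligand": "S-cyanopindolol"
}
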