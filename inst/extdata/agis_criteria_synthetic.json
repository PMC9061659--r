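{
  "version": "perisim-synthetic-1",
  "note": "Synthetic reconstruction of the AGIS defect-scoring criteria. The published scale's structure is kept (nasal sector max 2, superior and inferior hemifields max 9 each, total 0-20, cluster- and depth-based points) but the per-location depth thresholds and the depth rule are package choices: depth points use a minimum site count rather than a fraction of depressed sites so that the score is monotone under pointwise depression. Edit this file to explore other criteria.",
  "nasal": {
    "sites": [[-15, 3], [-21, 3], [-27, 3], [-15, -3], [-21, -3], [-27, -3]],
    "depth_db": 5,
    "min_contiguous": 3,
    "total_depth_db": 12
  },
  "hemifield": {
    "depth_db_central": 6,
    "depth_db_peripheral": 8,
    "peripheral_ecc": 15,
    "min_cluster": 3,
    "extent_breaks": [3, 6, 13, 21],
    "extent_points": [1, 2, 3, 4],
    "depth_levels": [12, 16, 20, 24, 28],
    "depth_min_sites": 3
  },
  "score_max": 20
}
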