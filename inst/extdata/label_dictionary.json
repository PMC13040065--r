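{
  "description": "Integer label codes used by fetal brain label volumes. TB (1) marks generic total-brain tissue; the total-brain mask is every non-zero voxel. The cortical plate mask is the union of CoP (2) and the five lobe codes (12-16).",
  "labels": {
    "TB": 1,
    "CoP": 2,
    "WM": 3,
    "DGM": 4,
    "CB": 5,
    "Th": 6,
    "LV": 7,
    "ChP": 8,
    "FH": 9,
    "BS": 10,
    "CSP": 11,
    "FL": 12,
    "TL": 13,
    "PL": 14,
    "OL": 15,
    "IL": 16
  },
  "long_names": {
    "TB": "total brain (generic tissue)",
    "CoP": "cortical plate (unlobed)",
    "WM": "white matter",
    "DGM": "deep grey matter",
    "CB": "cerebellum",
    "Th": "thalamus",
    "LV": "lateral ventricle",
    "ChP": "choroid plexus",
    "FH": "frontal horn",
    "BS": "brainstem",
    "CSP": "cavum septum pellucidum",
    "FL": "frontal lobe cortical plate",
    "TL": "temporal lobe cortical plate",
    "PL": "parietal lobe cortical plate",
    "OL": "occipital lobe cortical plate",
    "IL": "insular lobe cortical plate"
  }
}
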