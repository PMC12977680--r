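{
  "spec": {
    "n_genes": 30,
    "length_range": [80, 150],
    "tissues": ["wing_disc", "fat_body", "muscle"],
    "enrichment": {
      "wing_disc": 1,
      "fat_body": 3,
      "muscle": 1
    },
    "focus_set": ["ACT", "ACC"],
    "depth": 500,
    "dispersion": 10,
    "de_fold": 4,
    "size_factors": {},
    "gc3_bias": 1.5,
    "seed": 42
  },
  "home_tissue": {
    "g00001": "wing_disc",
    "g00002": "fat_body",
    "g00003": "muscle",
    "g00004": "wing_disc",
    "g00005": "fat_body",
    "g00006": "muscle",
    "g00007": "wing_disc",
    "g00008": "fat_body",
    "g00009": "muscle",
    "g00010": "wing_disc",
    "g00011": "fat_body",
    "g00012": "muscle",
    "g00013": "wing_disc",
    "g00014": "fat_body",
    "g00015": "muscle",
    "g00016": "wing_disc",
    "g00017": "fat_body",
    "g00018": "muscle",
    "g00019": "wing_disc",
    "g00020": "fat_body",
    "g00021": "muscle",
    "g00022": "wing_disc",
    "g00023": "fat_body",
    "g00024": "muscle",
    "g00025": "wing_disc",
    "g00026": "fat_body",
    "g00027": "muscle",
    "g00028": "wing_disc",
    "g00029": "fat_body",
    "g00030": "muscle"
  },
  "expected_bias_de_genes": {
    "wing_disc": {
      "ACT": 0.85714285714,
      "ACC": 0.85714285714
    },
    "fat_body": {
      "ACT": 1.2857142857,
      "ACC": 1.2857142857
    },
    "muscle": {
      "ACT": 0.85714285714,
      "ACC": 0.85714285714
    }
  },
  "expected_bias_all_genes": {
    "wing_disc": {
      "ACT": 0.92857142857,
      "ACC": 0.92857142857
    },
    "fat_body": {
      "ACT": 1.1428571429,
      "ACC": 1.1428571429
    },
    "muscle": {
      "ACT": 0.92857142857,
      "ACC": 0.92857142857
    }
  }
}
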