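[
  {
    "organism": "Variovorax paradoxus",
    "genome_accession": "EXAMPLE_000001",
    "cluster_index": 3,
    "cluster_type": "NRPS-T1PKS",
    "modules": [
      {"NRPSpredictor2": "pk", "Stachelhaus": "pk", "Minowa": "pk"},
      {"NRPSpredictor2": "ser", "Stachelhaus": "gly", "Minowa": "thr"},
      {"NRPSpredictor2": "ohmal", "Stachelhaus": "ohmal", "Minowa": "ohmal"},
      {"NRPSpredictor2": "ser", "Stachelhaus": "ser", "Minowa": "ser"},
      {"NRPSpredictor2": "orn", "Stachelhaus": "orn", "Minowa": "orn"},
      {"NRPSpredictor2": "thr", "Stachelhaus": "thr", "Minowa": "thr"},
      {"NRPSpredictor2": "asp", "Stachelhaus": "asp", "Minowa": "asp"}
    ],
    "known_match": {
      "compound_name": "Delftibactin",
      "mibig_id": "BGC0000984_c1",
      "identity_percent": 91
    }
  },
  {
    "organism": "Burkholderia thailandensis",
    "genome_accession": "EXAMPLE_000002",
    "cluster_index": 5,
    "cluster_type": "NRPS",
    "modules": [],
    "known_match": {
      "compound_name": "Burkholdac",
      "mibig_id": "BGC0000964_c1",
      "identity_percent": 100
    }
  }
]
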