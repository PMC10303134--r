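{
  "gene": "PAM",
  "transcript": "NM_000919.3",
  "cds_length_bp": 2922,
  "protein_length_aa": 974,
  "domains": [
    {"name": "N-terminus", "start_aa": 1, "end_aa": 36},
    {"name": "PHMcc", "start_aa": 37, "end_aa": 356},
    {"name": "linker", "start_aa": 357, "end_aa": 497},
    {"name": "PALcc", "start_aa": 498, "end_aa": 820},
    {"name": "C-terminus", "start_aa": 821, "end_aa": 974}
  ]
}
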