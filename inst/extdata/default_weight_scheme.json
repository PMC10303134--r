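{
  "base_weights": {
    "utr": 5,
    "synonymous": 5,
    "splice_region": 5,
    "protein_altering": 10,
    "start_lost": 20,
    "stop_lost": 20,
    "inframe_indel": 20,
    "frameshift": 75,
    "nonsense": 75,
    "splice_acceptor": 75,
    "splice_donor": 75,
    "transcript_ablation": 100
  },
  "missense_base": 20,
  "polyphen_increments": {
    "probably_damaging": 20,
    "possibly_damaging": 10,
    "unknown": 5,
    "benign": 0
  },
  "sift_increments": {
    "deleterious": 20,
    "deleterious_low_confidence": 20,
    "tolerated": 0,
    "tolerated_low_confidence": 0,
    "missing": 0
  }
}
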