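{
  "n_domains": 12,
  "n_proteins": 40,
  "domains_per_protein": [1, 3],
  "n_organisms": 25,
  "seqs_per_organism": 1,
  "n_cols": 12,
  "gap_rate": 0.05,
  "n_true_pairs": 2,
  "lambda_true": 0.8,
  "target_mi": 1.5,
  "coevo_alphabet": 20,
  "fn": 0.1,
  "fp": 0,
  "n_positive": 40,
  "n_negative": 40,
  "n_confound_pairs": 0,
  "min_pair_occurrence": 8
}
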