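# Reference fixtures

Small plain-text reference tables used by the validation tests and the
acceptance script.

- `published_kolmogorov_*.tsv`, `published_phi_*.tsv` — pairwise
  Kolmogorov-distance and Phi-correlation matrices for WGA replicate
  comparisons (REPLI-g / GenomiPhi amplified vs. unamplified human DNA
  samples), in the package's pairwise-matrix TSV dialect readable with
  `read_pairwise_matrix()`.  Group medians are recomputed with
  `matrix_median()`, never stored.
- `cftr_sequencing_primers.tsv` — bidirectional sequencing primer panel for
  a ~2 kb CFTR region (1-based inclusive coordinates); amplicon lengths are
  recomputed from the coordinates with `amplicon_length()`.
- `wga_sequencing_counts.tsv` — nucleotides examined and mutation counts per
  sample/kit from the bidirectional concordance screen.
- `wga_exclusion_counts.tsv` — excluded base counts per kit out of the
  aligned total, input to `exclusion_rate()`.
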