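# Example protectMS pipeline configuration: a 15-mer RNA standard with a
# 5'-terminal GGACU motif protected by its complementary DNA probe.
# The standard's flank is a synthetic placeholder sequence.
assay:
  full_rna: {sequence: GGACUCGUAUCACGU, strand: RNA, end5: OH, end3: OH}
  motif_start: 1
  motif_end: 5
  probe: {sequence: AGTCC, strand: DNA, tag_mass_delta: 0}
  nuclease_end5: phosphate
  nuclease_end3: OH
  probe_target_ratio: 2
  digest_temp_C: 15
predict:
  min_frag_len: 2
  mass_type: mono
  mz_window: [700, 5000]
annotate:
  tolerance_da: 0.5
  noise_method: mad_low
metrics:
  sn_threshold: 10
simulate:
  ratios: [0.25, 0.5, 1, 2, 4]
  replicates: [2, 2, 4, 4, 2]
  total_pmol: 100
  response_factor: 10
  cv_shared: 0.20
  cv_indep: 0.05
  mz_jitter_sd: 0.05
  n_decoys: 40
  decoy_noise_level: 7
seed: 1
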