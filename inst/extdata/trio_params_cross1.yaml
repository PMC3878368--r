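# Synthetic trio generator parameters calibrated to the genomic
# fingerprints and methylation table of cross 1 (see ?trio_sim_params).
n_fragments: 520
p_shared: 0.3673076923076923
p_female_only: 0.3153846153846154
p_male_only: 0.25
loss_maternal: 0.1097560975609756
loss_paternal: 0.2692307692307692
loss_common: 0.03664921465968586
p_novel: 0.1142857142857143
n_sites: 600
msap_state_probs:
  type_I: 0.456
  type_II: 0.284
  type_III: 0.22
  absent: 0.04
demethylation_shift: 0.076
replicate_dropout: 0
seed: 1
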