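# Frozen demonstration configuration: a small paired nutrient-deprivation
# study with the package's default thresholds. Used by examples and the
# determinism checks.
n_genes: 200
seed: 101
alpha_protein: 0.05
alpha_transcript: 0.05
l2fc_min: 1.0
rpkm_min: 2.0
logistic_fdr: 0.01
fisher_alpha: 0.05
set_t_q: 0.05
min_set_size: 5
top_k: 30
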