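# Demo pipeline configuration: a one-plate-scale synthetic screen enriched
# for actives so the association and model stages have signal to find.
seed: 1
n_chemicals: 24
p_active: 0.5
n_qc_triplicates: 3
cv_intensity: 0.05
alpha: 0.1
k_folds: 3
n_assays: 12
n_informative: 3
model_output: diff_decrease
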