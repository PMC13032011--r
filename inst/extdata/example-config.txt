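# unitcausal run configuration (key = value; flags override)
seed = 1
alpha = 0.05
max_depth = 3
grid_num = 10
bins_k = 10
epochs = 200
lr = 0.01
batch_size = 32
ensemble_gbdt = 10
ensemble_rf = 1
refute_relative_threshold = 0.10
refute_absolute_threshold = 0.05
refute_reps = 20
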