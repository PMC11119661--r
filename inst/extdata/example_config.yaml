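n_starts: 20
seed: 1
lambda_penalty: 0.001
near_opt_tolerance: 0.05
error_threshold: 0.1
bifurcation_points: 200
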