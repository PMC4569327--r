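# Desk-scale exploration of the built-in flocking model.
# Bounds and pattern-space discretisation default to the model's own
# (Table-style bounds relative to the environment; steps 1, 0.2, 0.1 with
# the -1 lower clamp on relative diffusion).
model: flocking
mu: 150
max_evaluations: 3000
replications: 5
reeval_prob: 0.01
sbx_eta: 2
master_seed: 1
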