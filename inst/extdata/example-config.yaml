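# Half-adaptive design analysed with the NDLM under the U-shaped truth.
scenario: S3_half_adaptive
profile: ushape
model: ndlm
doses: [0, 0.03, 0.3, 3, 10, 20, 30]
n_sims: 200
seed: 1
decision:
  interim_success_prob: 0.95
  interim_futility_prob: 0.20
  final_csd: 0.95
  final_success_prob: 0.70
mcmc:
  n_burnin: 500
  n_retained: 2500
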