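# FN-MDMC fitted to the visual-auditory task (aggregated data)
mu_r: 315.0
mu_rn: 302.0
sigma_r: 35.3
start_shape: 3.5
boundary: 55.6
mu_c: 0.58
automatic:
  visual:
    amplitude: 16.7
    tau: 46.6
    shape: 2
  auditory:
    amplitude: 5.3
    tau: 32.0
    shape: 2
sigma: 4
dt: 1
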