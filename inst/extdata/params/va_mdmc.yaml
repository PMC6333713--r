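# MDMC fitted to the visual-auditory task (aggregated data)
mu_r: 311.0
sigma_r: 40.5
start_shape: 2.7
boundary: 57.7
mu_c: 0.62
automatic:
  visual:
    amplitude: 15.1
    tau: 51.4
    shape: 2
  auditory:
    amplitude: 6.5
    tau: 35.5
    shape: 2
sigma: 4
dt: 1
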