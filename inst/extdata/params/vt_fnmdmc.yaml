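# FN-MDMC fitted to the visual-tactile task (aggregated data)
mu_r: 317.0
mu_rn: 303.0
sigma_r: 36.8
start_shape: 2.9
boundary: 64.1
mu_c: 0.66
automatic:
  visual:
    amplitude: 19.8
    tau: 38.5
    shape: 2
  tactile:
    amplitude: 7.1
    tau: 28.2
    shape: 2
sigma: 4
dt: 1
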