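# MDMC fitted to the visual-tactile task (aggregated data)
mu_r: 313.0
sigma_r: 33.4
start_shape: 3.1
boundary: 54.6
mu_c: 0.52
automatic:
  visual:
    amplitude: 13.4
    tau: 39.0
    shape: 2
  tactile:
    amplitude: 6.1
    tau: 28.5
    shape: 2
sigma: 4
dt: 1
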