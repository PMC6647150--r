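# Reference configuration: FHN neuron in the excitable regime
I = 0.265
alpha = 0.7
beta = 0.75
epsilon = 0.08
noise.kind = additive
noise.sigma0 = 0.01
sim.dt = 0.01
sim.T = 1000
sim.seed = 1
sim.v0 = -1.00125
sim.w0 = -0.4
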