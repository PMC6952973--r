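alpha1: 1
alpha2: 30
alpha3: 1
alpha4: 7
delta: 4
gamma: 1
omega: 0.6
nu: 8
k: 20
vth: 0.25
eps_xa: 0.001
eps_xn: 0.001
eps_ya: 0
eps_w: 0
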