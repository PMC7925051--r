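# example run configuration: bistable operating point, exact gate
Je = 32
Ji = 8
eta_bar = -5
delta = 1
Vth = 50
gate_width = pi_r
N_e = 1000
N_i = 1000
dt = 0.001
seed = 1
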