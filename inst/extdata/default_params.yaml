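# Central model parameters (flat key-value; units as in model_params()).
alpha: 1.3e-3
alpha_sd: 7.0e-4
Ka: 240.0
Ka_sd: 90.0
rho_dna: 390.0
rho_dna_sd: 90.0
L: 14.5
dH0: -68.5
dH0_sd: 3.0
dS0: -193.5
dS0_sd: 8.0
rho0: 0.6
T0: -3.0
R0: 10.0
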