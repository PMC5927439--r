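# Default parameter profile for the electrocyte posterior-membrane model.
# Flat key-value; keys match the arguments of electrocyte_params().
# Units: capacitance nF; conductances uS; potentials mV; temperature K;
# rate prefactors ms^-1; voltage sensitivities mV^-1; p_na mm^3/s;
# concentrations mM.
# Note: na_in is 13.5 mM, consistent with the fixed e_na of 55 mV and an
# AChR (two-ion GHK) reversal of +2.2 mV.
capacitance: 50
g_na_max: 700
g_k_max: 2000
g_leak: 5
gamma: 0.02
e_na: 55
e_k: -94
e_leak: -94
temperature: 293.15
k_alpha_m: 8.03
eta_alpha_m: 0.0037
k_beta_m: 0.2195
eta_beta_m: -0.0763
k_alpha_h: 0.02247
eta_alpha_h: -0.06802
beta_h_max: 3.33
beta_h_vhalf: -30
beta_h_k: 9
k_alpha_n: 2.135
eta_alpha_n: 0.03792
k_beta_n: 0.3524
eta_beta_n: -0.01552
p_na: 0.00016
pk_over_pna: 1.11
na_in: 13.5
na_out: 120
k_in: 89
k_out: 2.16
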