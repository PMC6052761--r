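A1:
  value: 1.0
  provenance: placeholder
A2:
  value: 0.5
  provenance: placeholder
A3:
  value: 0.35
  provenance: placeholder
A4:
  value: 0.5
  provenance: placeholder
A5:
  value: 0.35
  provenance: placeholder
eps_T:
  value: 2.0
  provenance: placeholder
eps_E:
  value: 2.0
  provenance: placeholder
eps_TE:
  value: 0.5
  provenance: placeholder
eps_e:
  value: 0.0
  provenance: placeholder
Mbar:
  value: 1.0
  provenance: placeholder
k_alpha:
  value: 1.0
  provenance: placeholder
k_beta:
  value: 1.0
  provenance: placeholder
R_alpha_beta:
  value: 1.0
  provenance: placeholder
gamma_T:
  value: 1.0
  provenance: placeholder
gamma_E:
  value: 1.0
  provenance: placeholder
L1E:
  value: 2.0
  provenance: placeholder
L2E:
  value: 1.0
  provenance: placeholder
L1C:
  value: 1.0
  provenance: placeholder
L2C:
  value: 0.5
  provenance: placeholder
estar_E:
  value: 0.05
  provenance: placeholder
estar_C:
  value: 0.0
  provenance: placeholder
D_n:
  value:
  - 12.0
  - 12.0
  - 15.0
  provenance: placeholder
D_g:
  value:
  - 8.0
  - 8.0
  - 10.0
  provenance: placeholder
D_w:
  value:
  - 30.0
  - 35.0
  - 40.0
  provenance: placeholder
D_l:
  value:
  - 20.0
  - 20.0
  - 25.0
  provenance: placeholder
D_b:
  value:
  - 20.0
  - 20.0
  - 25.0
  provenance: placeholder
D_a:
  value:
  - 25.0
  - 25.0
  - 30.0
  provenance: placeholder
D_s:
  value:
  - 20.0
  - 20.0
  - 25.0
  provenance: placeholder
D_r:
  value:
  - 20.0
  - 20.0
  - 25.0
  provenance: placeholder
D_tgf:
  value:
  - 8.0
  - 8.0
  - 10.0
  provenance: placeholder
D_taf:
  value:
  - 8.0
  - 8.0
  - 10.0
  provenance: placeholder
D_m:
  value:
  - 5.0
  - 5.0
  - 5.0
  provenance: placeholder
D_F:
  value: 0.5
  provenance: placeholder
D_BnE:
  value: 0.1
  provenance: placeholder
D_LnE:
  value: 0.1
  provenance: placeholder
k_n1:
  value:
  - 1.0
  - 1.0
  - 1.0
  provenance: placeholder
k_n2:
  value:
  - 0.5
  - 5.0
  - 0.05
  provenance: placeholder
k_g1:
  value:
  - 1.0
  - 1.0
  - 1.0
  provenance: placeholder
k_g2:
  value:
  - 0.2
  - 2.0
  - 0.02
  provenance: placeholder
k_w:
  value:
  - 1.0
  - 1.0
  - 1.0
  provenance: placeholder
k_l:
  value:
  - 1.0
  - 1.0
  - 1.0
  provenance: placeholder
k_f:
  value: 1.0
  provenance: placeholder
k_r:
  value: 1.0
  provenance: placeholder
R_g_n:
  value: 1.0
  provenance: placeholder
z_l:
  value: -1.0
  provenance: placeholder
z_b:
  value: -1.0
  provenance: placeholder
z_a:
  value: 1.0
  provenance: placeholder
z_s:
  value: 1.0
  provenance: placeholder
z_r:
  value: -1.0
  provenance: placeholder
lambda_tgf:
  value: 1.0
  provenance: placeholder
lambda_de_tgf:
  value: 0.5
  provenance: placeholder
lambda_U_tgf:
  value: 0.5
  provenance: placeholder
lambda_taf:
  value: 1.0
  provenance: placeholder
lambda_de_taf:
  value: 0.5
  provenance: placeholder
lambda_U_taf:
  value: 0.5
  provenance: placeholder
lambda_prod_m:
  value: 1.0
  provenance: placeholder
lambda_de_m:
  value: 1.0
  provenance: placeholder
lambda_M_F:
  value: 0.5
  provenance: placeholder
lambda_A_F:
  value: 0.1
  provenance: placeholder
lambda_sp_B:
  value: 0.5
  provenance: placeholder
lambda_cr_B:
  value: 0.25
  provenance: placeholder
lambda_sp_L:
  value: 0.5
  provenance: placeholder
lambda_cr_L:
  value: 0.25
  provenance: placeholder
p_crush:
  value: 0.5
  provenance: placeholder
chi_che_BnE:
  value: 0.2
  provenance: placeholder
chi_hap_BnE:
  value: 0.2
  provenance: placeholder
A_che_BnE:
  value: 1.0
  provenance: placeholder
A_hap_BnE:
  value: 1.0
  provenance: placeholder
chi_che_LnE:
  value: 0.2
  provenance: placeholder
chi_hap_LnE:
  value: 0.2
  provenance: placeholder
A_che_LnE:
  value: 1.0
  provenance: placeholder
A_hap_LnE:
  value: 1.0
  provenance: placeholder
lambda_M_V:
  value: 1.0
  provenance: model
lambda_N_V:
  value: 3.0
  provenance: model
lambda_L_D:
  value: 1.0
  provenance: model
lambda_F_E:
  value: 5.0
  provenance: model
lambda_de_E:
  value: 5.0
  provenance: model
F_n_EF:
  value: 2.0
  provenance: model
n_h:
  value: 0.3
  provenance: model
n_v_V:
  value: 0.21
  provenance: model
g_v_V:
  value: 0.1
  provenance: model
n_v_F:
  value: 0.21
  provenance: model
tgf_F_E:
  value: 0.2
  provenance: model
B_inf:
  value: 0.2
  provenance: model
L_inf:
  value: 0.2
  provenance: model
phi_V_seed:
  value: 0.65
  provenance: model
phi_E0:
  value: 0.35
  provenance: model
seed_side:
  value: 10.0
  provenance: placeholder
F_E0:
  value: 0.1
  provenance: placeholder
supply_ref:
  value: 0.07
  provenance: placeholder
sprout_fractions:
  value:
  - 0.1
  - 0.2
  - 0.3
  - 0.4
  - 0.5
  - 0.6
  - 0.7
  - 0.8
  provenance: placeholder
Q3:
  value: smoothstep x^2(3-2x)
  provenance: placeholder
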