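gqoi,group,tvp_mmHg,mean,sem,n
L_FE_bar,anterior,10,0.29,0.02,3
L_FE_bar,anterior,20,0.31,0.01,5
L_FE_bar,anterior,30,0.30,0.01,3
L_FE_bar,left_right,10,0.36,0.01,6
L_FE_bar,left_right,20,0.35,0.01,10
L_FE_bar,left_right,30,0.32,0.01,6
L_BA_bar,anterior,10,0.41,0.01,3
L_BA_bar,anterior,20,0.41,0.01,5
L_BA_bar,anterior,30,0.41,0.01,3
L_BA_bar,left_right,10,0.49,0.01,6
L_BA_bar,left_right,20,0.47,0.01,10
L_BA_bar,left_right,30,0.46,0.01,6
H_bar,valve,10,0.14,0.00,3
H_bar,valve,20,0.13,0.00,5
H_bar,valve,30,0.13,0.00,3
w_bar_x100,valve,10,0.42,0.04,3
w_bar_x100,valve,20,0.36,0.02,5
w_bar_x100,valve,30,0.42,0.04,3
beta_deg,valve,10,11,2,3
beta_deg,valve,20,10,2,5
beta_deg,valve,30,11,1,3
L_gamma_um,valve,10,4646,20,3
L_gamma_um,valve,20,5206,67,5
L_gamma_um,valve,30,5219,206,3
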