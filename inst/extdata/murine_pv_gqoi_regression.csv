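gqoi,group,model,intercept,intercept_sem,slope_display,slope_sem_display,slope_scale,p_value
L_FE_bar,anterior,linear,0.29,0.02,0.03,0.10,100,0.75
L_FE_bar,left_right,linear,0.38,0.01,-0.20,0.05,100,0.00
L_BA_bar,anterior,linear,0.41,0.02,0.01,0.10,100,0.89
L_BA_bar,left_right,linear,0.49,0.02,-0.11,0.09,100,0.21
H_bar,valve,linear,0.15,0.00,-0.08,0.02,100,0.01
w_bar_x100,valve,constant,0.39,0.09,NA,NA,100,NA
beta_deg,valve,constant,10,1,NA,NA,1,NA
L_gamma_um,valve,linear,4554,257,26,12,1,0.06
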