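variety,temperature_c,d_eff_m2_s,r2
smelling,50,5.75e-10,0.9650
smelling,60,7.34e-10,0.9424
smelling,70,10.62e-10,0.9276
smelling,80,15.16e-10,0.9126
pout,50,3.47e-10,0.9753
pout,60,4.67e-10,0.9646
pout,70,7.29e-10,0.9663
pout,80,8.59e-10,0.9386
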