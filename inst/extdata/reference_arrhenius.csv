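variety,d0_m2_s,ea_kj_mol,r2
smelling,5.67e-5,31.01,0.9875
pout,2.56e-5,30.11,0.9777
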