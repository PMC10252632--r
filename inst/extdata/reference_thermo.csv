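variety,temperature_c,dh_kj_mol,ds_kj_mol_k,dg_kj_mol
smelling,50,28.3243,-0.3269,133.9500
smelling,60,28.2412,-0.3271,137.2199
smelling,70,28.1581,-0.3274,140.4923
smelling,80,28.0749,-0.3276,143.7671
pout,50,27.4223,-0.3335,135.1890
pout,60,27.3392,-0.3337,138.5252
pout,70,27.2561,-0.3340,141.8638
pout,80,27.1729,-0.3342,145.2049
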