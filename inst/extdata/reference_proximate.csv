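label,variety,treatment,basis,water_pct,protein_pct,lipid_pct,ash_pct,carbohydrate_printed,energy_printed
smelling_in_natura,smelling,in_natura,dry,91.88,19.38,2.11,6.83,71.67,383.23
smelling_50,smelling,50,dry,9.34,14.87,3.21,5.60,76.32,393.65
smelling_60,smelling,60,dry,9.06,15.26,4.03,6.30,74.41,394.97
smelling_70,smelling,70,dry,8.92,18.40,3.95,6.73,70.92,392.83
smelling_80,smelling,80,dry,7.93,18.59,3.86,6.76,70.80,392.29
pout_in_natura,pout,in_natura,dry,83.30,14.96,2.10,6.76,76.18,383.43
pout_50,pout,50,dry,11.95,14.79,6.02,5.37,73.82,408.63
pout_60,pout,60,dry,10.41,15.83,4.58,6.23,73.36,398.00
pout_70,pout,70,dry,7.25,15.34,5.78,6.47,72.41,403.04
pout_80,pout,80,dry,6.56,15.39,7.70,6.21,70.71,413.65
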