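variety,temperature_c,drying_time_min,water_wb_pct,water_db_pct
smelling,50,1250,6.34,6.77
smelling,60,890,7.33,7.91
smelling,70,710,6.47,6.92
smelling,80,410,4.48,4.70
pout,50,1190,5.65,6.33
pout,60,830,5.02,5.29
pout,70,650,4.80,5.04
pout,80,530,4.32,4.52
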