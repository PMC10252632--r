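variety,temperature_c,model,param,value
smelling,50,two_term,a,0.5428
smelling,50,two_term,k0,0.0035
smelling,50,two_term,b,0.4583
smelling,50,two_term,k1,0.0035
smelling,60,two_term,a,0.5102
smelling,60,two_term,k0,0.0046
smelling,60,two_term,b,0.5081
smelling,60,two_term,k1,0.0046
smelling,70,two_term,a,0.5237
smelling,70,two_term,k0,0.0068
smelling,70,two_term,b,0.5237
smelling,70,two_term,k1,0.0068
smelling,80,two_term,a,0.5318
smelling,80,two_term,k0,0.0098
smelling,80,two_term,b,0.5318
smelling,80,two_term,k1,0.0098
smelling,50,henderson_pabis,a,1.0012
smelling,50,henderson_pabis,k,0.0035
smelling,60,henderson_pabis,a,1.0183
smelling,60,henderson_pabis,k,0.0046
smelling,70,henderson_pabis,a,1.0475
smelling,70,henderson_pabis,k,0.0068
smelling,80,henderson_pabis,a,1.0588
smelling,80,henderson_pabis,k,0.0097
smelling,50,henderson_pabis_modified,a,0.3365
smelling,50,henderson_pabis_modified,k,0.0035
smelling,50,henderson_pabis_modified,b,0.3320
smelling,50,henderson_pabis_modified,k0,0.0035
smelling,50,henderson_pabis_modified,c,0.3326
smelling,50,henderson_pabis_modified,k1,0.0035
smelling,60,henderson_pabis_modified,a,0.3338
smelling,60,henderson_pabis_modified,k,0.0046
smelling,60,henderson_pabis_modified,b,0.3347
smelling,60,henderson_pabis_modified,k0,0.0046
smelling,60,henderson_pabis_modified,c,0.3498
smelling,60,henderson_pabis_modified,k1,0.0046
smelling,70,henderson_pabis_modified,a,0.3490
smelling,70,henderson_pabis_modified,k,0.0068
smelling,70,henderson_pabis_modified,b,0.3490
smelling,70,henderson_pabis_modified,k0,0.0068
smelling,70,henderson_pabis_modified,c,0.3490
smelling,70,henderson_pabis_modified,k1,0.0068
smelling,80,henderson_pabis_modified,a,0.3529
smelling,80,henderson_pabis_modified,k,0.0097
smelling,80,henderson_pabis_modified,b,0.3529
smelling,80,henderson_pabis_modified,k0,0.0097
smelling,80,henderson_pabis_modified,c,0.3529
smelling,80,henderson_pabis_modified,k1,0.0097
smelling,50,logarithmic,a,1.0268
smelling,50,logarithmic,k,0.0033
smelling,50,logarithmic,c,-0.0305
smelling,60,logarithmic,a,1.0753
smelling,60,logarithmic,k,0.0040
smelling,60,logarithmic,c,-0.0656
smelling,70,logarithmic,a,1.1000
smelling,70,logarithmic,k,0.0061
smelling,70,logarithmic,c,-0.0611
smelling,80,logarithmic,a,1.1442
smelling,80,logarithmic,k,0.0080
smelling,80,logarithmic,c,-0.0999
smelling,50,logistic,a0,0.0415
smelling,50,logistic,a,0.0415
smelling,50,logistic,k,0.0035
smelling,60,logistic,a0,0.0714
smelling,60,logistic,a,0.0701
smelling,60,logistic,k,0.0046
smelling,70,logistic,a0,0.0766
smelling,70,logistic,a,0.0732
smelling,70,logistic,k,0.0068
smelling,80,logistic,a0,0.1837
smelling,80,logistic,a,0.1735
smelling,80,logistic,k,0.0097
smelling,50,midilli,a,0.9938
smelling,50,midilli,k,0.0031
smelling,50,midilli,n,1.0200
smelling,50,midilli,b,-0.00002
smelling,60,midilli,a,0.9839
smelling,60,midilli,k,0.0018
smelling,60,midilli,n,1.1691
smelling,60,midilli,b,-0.00003
smelling,70,midilli,a,0.9923
smelling,70,midilli,k,0.0015
smelling,70,midilli,n,1.2874
smelling,70,midilli,b,-0.00002
smelling,80,midilli,a,0.9895
smelling,80,midilli,k,0.0018
smelling,80,midilli,n,1.3451
smelling,80,midilli,b,-0.00005
smelling,50,newton,k,0.0035
smelling,60,newton,k,0.0045
smelling,70,newton,k,0.0064
smelling,80,newton,k,0.0089
smelling,50,page,k,0.0030
smelling,50,page,n,1.0309
smelling,60,page,k,0.0021
smelling,60,page,n,1.1445
smelling,70,page,k,0.0017
smelling,70,page,n,1.2758
smelling,80,page,k,0.0020
smelling,80,page,n,1.3329
smelling,50,thompson,a,-8206.30
smelling,50,thompson,b,5.3873
smelling,60,thompson,a,-4878.02
smelling,60,thompson,b,4.6680
smelling,70,thompson,a,-2551.27
smelling,70,thompson,b,4.0268
smelling,80,thompson,a,-4143.82
smelling,80,thompson,b,6.0725
smelling,50,verma,a,-0.0019
smelling,50,verma,k,0.1944
smelling,50,verma,k1,0.0035
smelling,60,verma,a,-0.1863
smelling,60,verma,k,0.0186
smelling,60,verma,k1,0.0055
smelling,70,verma,a,-7.1194
smelling,70,verma,k,0.0130
smelling,70,verma,k1,0.0118
smelling,80,verma,a,-14.5638
smelling,80,verma,k,0.0184
smelling,80,verma,k1,0.0175
pout,50,two_term,a,0.0453
pout,50,two_term,k0,0.1071
pout,50,two_term,b,0.9538
pout,50,two_term,k1,0.0065
pout,60,two_term,a,0.5715
pout,60,two_term,k0,0.0096
pout,60,two_term,b,0.4427
pout,60,two_term,k1,0.0096
pout,70,two_term,a,0.5017
pout,70,two_term,k0,0.0149
pout,70,two_term,b,0.5017
pout,70,two_term,k1,0.0148
pout,80,two_term,a,0.5294
pout,80,two_term,k0,0.0152
pout,80,two_term,b,0.5294
pout,80,two_term,k1,0.0152
pout,50,henderson_pabis,a,0.9742
pout,50,henderson_pabis,k,0.0067
pout,60,henderson_pabis,a,1.0141
pout,60,henderson_pabis,k,0.0096
pout,70,henderson_pabis,a,1.0028
pout,70,henderson_pabis,k,0.0148
pout,80,henderson_pabis,a,1.0587
pout,80,henderson_pabis,k,0.0152
pout,50,henderson_pabis_modified,a,0.3246
pout,50,henderson_pabis_modified,k,0.0062
pout,50,henderson_pabis_modified,b,0.3246
pout,50,henderson_pabis_modified,k0,0.0062
pout,50,henderson_pabis_modified,c,0.3263
pout,50,henderson_pabis_modified,k1,0.0081
pout,60,henderson_pabis_modified,a,0.3382
pout,60,henderson_pabis_modified,k,0.0096
pout,60,henderson_pabis_modified,b,0.3382
pout,60,henderson_pabis_modified,k0,0.0096
pout,60,henderson_pabis_modified,c,0.3378
pout,60,henderson_pabis_modified,k1,0.0096
pout,70,henderson_pabis_modified,a,0.3342
pout,70,henderson_pabis_modified,k,0.0148
pout,70,henderson_pabis_modified,b,0.3342
pout,70,henderson_pabis_modified,k0,0.0148
pout,70,henderson_pabis_modified,c,0.3343
pout,70,henderson_pabis_modified,k1,0.0148
pout,80,henderson_pabis_modified,a,0.3530
pout,80,henderson_pabis_modified,k,0.0152
pout,80,henderson_pabis_modified,b,0.3530
pout,80,henderson_pabis_modified,k0,0.0152
pout,80,henderson_pabis_modified,c,0.3530
pout,80,henderson_pabis_modified,k1,0.0152
pout,50,logarithmic,a,0.9773
pout,50,logarithmic,k,0.0067
pout,50,logarithmic,c,-0.0039
pout,60,logarithmic,a,1.0270
pout,60,logarithmic,k,0.0092
pout,60,logarithmic,c,-0.0159
pout,70,logarithmic,a,1.0142
pout,70,logarithmic,k,0.0143
pout,70,logarithmic,c,-0.0147
pout,80,logarithmic,a,1.0851
pout,80,logarithmic,k,0.0142
pout,80,logarithmic,c,-0.0327
pout,50,logistic,a0,0.1219
pout,50,logistic,a,0.1251
pout,50,logistic,k,0.0067
pout,60,logistic,a0,0.1489
pout,60,logistic,a,0.1468
pout,60,logistic,k,0.0096
pout,70,logistic,a0,0.1035
pout,70,logistic,a,0.1032
pout,70,logistic,k,0.0148
pout,80,logistic,a0,0.1153
pout,80,logistic,a,0.1089
pout,80,logistic,k,0.0152
pout,50,midilli,a,0.9866
pout,50,midilli,k,0.0088
pout,50,midilli,n,0.9478
pout,50,midilli,b,-0.000008
pout,60,midilli,a,0.9907
pout,60,midilli,k,0.0059
pout,60,midilli,n,1.0963
pout,60,midilli,b,-0.000008
pout,70,midilli,a,0.9724
pout,70,midilli,k,0.0086
pout,70,midilli,n,1.1207
pout,70,midilli,b,-0.000006
pout,80,midilli,a,0.9852
pout,80,midilli,k,0.0033
pout,80,midilli,n,1.3463
pout,80,midilli,b,-0.000007
pout,50,newton,k,0.0071
pout,60,newton,k,0.0094
pout,70,newton,k,0.0148
pout,80,newton,k,0.0141
pout,50,page,k,0.0100
pout,50,page,n,0.9271
pout,60,page,k,0.0066
pout,60,page,n,1.0776
pout,70,page,k,0.0114
pout,70,page,n,1.0618
pout,80,page,k,0.0039
pout,80,page,n,1.3065
pout,50,thompson,a,-35.1148
pout,50,thompson,b,0.5118
pout,60,thompson,a,-2247.7001
pout,60,thompson,b,4.5874
pout,70,thompson,a,-4120.3012
pout,70,thompson,b,7.7995
pout,80,thompson,a,-4282.2716
pout,80,thompson,b,7.7620
pout,50,verma,a,-6.3939
pout,50,verma,k,0.0074
pout,50,verma,k1,0.0074
pout,60,verma,a,-3.4090
pout,60,verma,k,0.0059
pout,60,verma,k1,0.0066
pout,70,verma,a,-4.7678
pout,70,verma,k,0.0096
pout,70,verma,k1,0.0104
pout,80,verma,a,-2.8776
pout,80,verma,k,0.0075
pout,80,verma,k1,0.0089
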