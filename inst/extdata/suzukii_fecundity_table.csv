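temperature_C,preovip_mean_days,preovip_se_days,total_eggs_mean,total_eggs_se
13,1.9,0.3,39,4
18,2.2,0.2,120,10
20,1.5,0.3,160,20
24,1,1,210,10
25,1.6,0.2,190,7
26,1.3,0.2,170,10
27,2.4,0.2,140,3
28,2.2,0.5,110,20
29,2.8,0.4,70,5
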