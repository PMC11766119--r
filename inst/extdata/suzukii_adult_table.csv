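sex,temperature_C,mean_days,sd_days,mode_days,median_days,kurtosis,skewness
male,13,22,3,22,22,0.31,0.89
male,18,32,5,NA,38.7,-1.89,-0.14
male,20,40,10,45.3,41.8,-0.02,-0.96
male,24,26,7,24.3,25.7,0.10,-0.93
male,25,27,2,25.4,27,-0.79,-0.20
male,26,24,6,25.4,25.4,5.64,-2.24
male,27,25,1,25.4,25.4,-0.23,-0.81
male,28,19,8,8.4,17.4,-0.97,0.41
male,29,24,1,NA,23.4,-0.84,0.56
female,13,20,2,20,20,-0.009,-0.17
female,18,25.2,0.0,25.3,24.8,3.68,1.17
female,20,24,6,25.7,23.3,5.11,1.76
female,24,23,3,22.3,22.7,0.10,0.36
female,25,23,2,22,23.1,-0.53,0.43
female,26,22,2,21.3,21.7,-0.01,0.36
female,27,21,1,21.3,21.3,-0.97,-0.15
female,28,21,5,19.3,19.3,1.22,0.97
female,29,19.9,0.7,20.3,20.3,0.10,-0.96
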