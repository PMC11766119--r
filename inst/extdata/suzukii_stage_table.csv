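stage,temperature_C,mean_days,sd_days,mode_days,median_days,kurtosis,skewness,n_entered,n_survived
egg,6,9,1,10,9,-1.21,-0.44,50,13
egg,9,5,1,5,5,1.79,1.12,50,19
egg,13,3.3,0.8,3,3,-0.46,0.04,50,37
egg,18,1.5,0.3,1.6,1.6,0.89,-1.24,50,46
egg,20,1.4,0.3,1.7,1.3,0.84,-1.15,50,47
egg,24,0.9,0.3,0.6,1,-0.70,0.10,50,49
egg,25,0.9,0.3,0.6,0.8,-0.53,0.20,50,48
egg,26,0.8,0.2,1,0.8,-0.21,-0.08,50,48
egg,27,0.8,0.3,1,1,-0.59,0.03,50,44
egg,28,0.9,0.2,1,1,4.19,-2.00,50,39
egg,29,1.0,0.2,1,1,0.87,0.92,50,36
egg,31,1.2,0.2,1.1,1.2,-0.13,0.63,50,22
egg,32,1.6,0.1,1.5,1.6,-0.83,0.71,50,9
egg,33,1.75,0.08,NA,1.75,NA,0,50,3
L1,6,6.3,0.6,6,6,NA,1.73,13,3
L1,9,5.6,0.5,6,6,-2.26,-0.39,19,12
L1,13,4.5,0.5,5,5,-2.12,-0.14,37,30
L1,18,2.0,0.3,2,2,0.71,-0.80,46,40
L1,20,1.6,0.2,1.7,1.7,-0.39,0.04,47,40
L1,24,1.3,0.2,1.3,1.3,-0.50,-0.02,49,46
L1,25,1.2,0.1,1.3,1.3,-0.84,-1.09,48,45
L1,26,1.2,0.2,1.3,1.3,-2.01,-0.27,48,46
L1,27,1.0,0.05,1,1,41,6.40,44,41
L1,28,0.8,0.2,1,1,-2.11,-0.12,39,34
L1,29,1.0,0.2,1.1,1,3.45,1.30,36,28
L1,31,1.3,0.3,1.2,1.2,0.67,-0.09,22,12
L1,32,1.8,0.2,NA,1.8,1.50,1.19,9,4
L1,33,NA,NA,NA,NA,NA,NA,3,0
L2,6,NA,NA,NA,NA,NA,NA,3,0
L2,9,5.8,0.4,6,6,1.40,-1.78,12,10
L2,13,4.7,0.6,5,5,-0.48,0.23,30,27
L2,18,2.8,0.3,3,3,-0.35,-0.43,40,37
L2,20,2.5,0.3,2.6,2.5,-0.86,-0.04,40,38
L2,24,1.6,0.3,1.7,1.7,0.93,0.96,46,44
L2,25,1.4,0.1,1.3,1.3,4.36,2.48,45,43
L2,26,1.2,0.2,1.3,1.3,-0.63,0.38,46,42
L2,27,1.2,0.2,1.3,1.3,-1.61,-0.69,41,38
L2,28,1.1,0.2,1,1,-0.88,-0.19,34,32
L2,29,1.4,0.2,1.3,1.3,-0.64,0.18,28,21
L2,31,1.7,0.3,1.6,1.7,1.48,0.25,12,7
L2,32,NA,NA,NA,NA,NA,NA,4,0
L2,33,NA,NA,NA,NA,NA,NA,0,0
L3,6,NA,NA,NA,NA,NA,NA,0,0
L3,9,7.5,0.8,8,8,1.47,-1.50,10,9
L3,13,6.6,0.6,7,7,-0.72,0.28,27,25
L3,18,2.9,0.2,3,3,-0.88,-0.03,37,36
L3,20,2.4,0.2,2.3,2.3,-0.63,-0.14,38,38
L3,24,2.0,0.2,2,2,1.49,0.29,44,43
L3,25,1.7,0.2,1.7,1.7,-0.07,0.22,43,43
L3,26,1.5,0.2,1.3,1.3,-0.31,0.88,42,42
L3,27,1.4,0.2,1.3,1.3,-1.47,0.78,38,37
L3,28,1.4,0.3,1.3,1.3,-0.44,0.35,32,31
L3,29,1.8,0.3,1.7,1.8,-0.07,0.44,21,18
L3,31,2.3,0.1,NA,2.2,NA,0.93,7,3
L3,32,NA,NA,NA,NA,NA,NA,0,0
L3,33,NA,NA,NA,NA,NA,NA,0,0
pupa,6,NA,NA,NA,NA,NA,NA,0,0
pupa,9,NA,NA,NA,NA,NA,NA,9,0
pupa,13,13.1,0.9,13,13,-0.26,0.55,25,25
pupa,18,5.7,0.0,5.7,5.7,-0.58,-0.06,36,36
pupa,20,5.3,0.4,5.3,5.3,0.81,0.81,38,38
pupa,24,4.6,0.3,4.7,4.7,-0.33,-0.30,43,43
pupa,25,4.6,0.2,4.7,4.7,0.39,-0.30,43,43
pupa,26,4.4,0.3,4.3,4.3,-0.19,0.30,42,42
pupa,27,4.6,0.2,4.7,4.7,0.70,-0.34,37,37
pupa,28,4.7,0.3,4.7,4.7,-0.59,-0.07,31,31
pupa,29,5.0,0.5,5.5,5.2,-0.78,-0.21,18,17
pupa,31,NA,NA,NA,NA,NA,NA,3,0
pupa,32,NA,NA,NA,NA,NA,NA,0,0
pupa,33,NA,NA,NA,NA,NA,NA,0,0
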