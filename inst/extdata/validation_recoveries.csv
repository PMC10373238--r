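method,component,sample,recovery
cls,FV,1,99.98
cls,FV,2,101.94
cls,FV,3,101.91
cls,FV,4,101.55
cls,FV,5,101.83
cls,FV,6,101.61
cls,FV,7,101.77
cls,FV,8,100.17
cls,FV,9,100.03
cls,FV,10,101.7
cls,FV,11,101.46
cls,FV,12,101.66
cls,RV,1,99.05
cls,RV,2,99.59
cls,RV,3,99.59
cls,RV,4,99.55
cls,RV,5,99.5
cls,RV,6,99.48
cls,RV,7,99.58
cls,RV,8,99.03
cls,RV,9,99.04
cls,RV,10,99.5
cls,RV,11,99.54
cls,RV,12,99.57
pcr,FV,1,99.76
pcr,FV,2,100.01
pcr,FV,3,100.1
pcr,FV,4,100.02
pcr,FV,5,100.09
pcr,FV,6,100.07
pcr,FV,7,100.05
pcr,FV,8,99.83
pcr,FV,9,99.74
pcr,FV,10,100.04
pcr,FV,11,99.98
pcr,FV,12,99.99
pcr,RV,1,99.15
pcr,RV,2,100.04
pcr,RV,3,100.06
pcr,RV,4,100.16
pcr,RV,5,100.01
pcr,RV,6,100.08
pcr,RV,7,100.09
pcr,RV,8,99.22
pcr,RV,9,99.19
pcr,RV,10,100.03
pcr,RV,11,100.19
pcr,RV,12,100.1
pls,FV,1,99.76
pls,FV,2,100.01
pls,FV,3,100.1
pls,FV,4,100.02
pls,FV,5,100.09
pls,FV,6,100.07
pls,FV,7,100.05
pls,FV,8,99.83
pls,FV,9,99.74
pls,FV,10,100.04
pls,FV,11,99.98
pls,FV,12,99.99
pls,RV,1,99.99
pls,RV,2,100.05
pls,RV,3,100.04
pls,RV,4,100.01
pls,RV,5,99.96
pls,RV,6,99.94
pls,RV,7,100.03
pls,RV,8,99.98
pls,RV,9,99.99
pls,RV,10,99.96
pls,RV,11,100.01
pls,RV,12,100.03
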