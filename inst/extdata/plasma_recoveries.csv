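method,component,added_fv,added_rv,recovery
cls,FV,1,1,95.28
cls,FV,2,1,95.54
cls,FV,1,2,92.88
cls,FV,1,3,93.35
cls,FV,3,1,94.26
cls,RV,1,1,94.85
cls,RV,2,1,93.58
cls,RV,1,2,95.24
cls,RV,1,3,94.25
cls,RV,3,1,92.88
pcr,FV,1,1,94
pcr,FV,2,1,94.54
pcr,FV,1,2,92.57
pcr,FV,1,3,92.71
pcr,FV,3,1,93.55
pcr,RV,1,1,94.85
pcr,RV,2,1,93.58
pcr,RV,1,2,94.25
pcr,RV,1,3,94.25
pcr,RV,3,1,92.88
pls,FV,1,1,94.25
pls,FV,2,1,95.66
pls,FV,1,2,93.1
pls,FV,1,3,94.15
pls,FV,3,1,93.15
pls,RV,1,1,94.12
pls,RV,2,1,94.15
pls,RV,1,2,94.25
pls,RV,1,3,95.25
pls,RV,3,1,93.66
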