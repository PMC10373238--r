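method,component,base_taken,base_found,pure_added,pure_found
cls,FV,2,1.99,3,3.02
cls,FV,2,1.99,5,4.98
cls,FV,2,1.99,7,7.09
cls,RV,4,4.01,4,4.03
cls,RV,4,4.01,6,5.95
cls,RV,4,4.01,8,8.05
pcr,FV,2,1.99,3,2.98
pcr,FV,2,1.99,5,5.05
pcr,FV,2,1.99,7,6.94
pcr,RV,4,3.98,4,3.95
pcr,RV,4,3.98,6,5.97
pcr,RV,4,3.98,8,7.87
pls,FV,2,2,3,3.02
pls,FV,2,2,5,4.98
pls,FV,2,2,7,6.96
pls,RV,4,4.02,4,4.05
pls,RV,4,4.02,6,6.08
pls,RV,4,4.02,8,8.15
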