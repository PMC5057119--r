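sex,class_lower,class_upper,n,mean_dcl,se_dcl,mean_dw,se_dw
M,28,30,1,14.9,0.0,47.3,0.0
M,30,32,3,13.2,0.5,49.2,2.6
M,32,34,2,9.1,2.3,27.4,2.9
M,34,36,3,12.8,1.6,49.6,4.8
M,36,38,3,10.9,1.7,46.5,9.8
F,28,30,1,5.5,0.9,14.6,0.0
F,30,32,9,4.9,0.6,13.1,2.6
F,32,34,5,3.7,0.7,11.2,2.3
F,34,36,7,4.8,0.4,15.7,2.5
F,36,38,3,4.2,0.1,11.3,1.0
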