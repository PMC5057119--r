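sex,class_lower,class_upper,n,mean_dcl,se_dcl,mean_dtl,se_dtl,mean_dw,se_dw
M,26,28,1,7.3,0.0,24.2,0.0,16.2,0.0
M,28,30,5,6.5,0.7,21.6,2.5,16.6,2.2
M,30,32,18,6.0,0.4,19.9,1.4,17.3,1.4
M,32,34,27,4.7,0.5,15.7,1.5,15.1,1.7
M,34,36,30,4.9,0.4,16.1,1.4,17.9,1.9
M,36,38,14,4.1,0.4,13.7,1.3,16.5,1.9
M,38,40,4,5.3,1.6,17.5,5.2,24.1,8.2
F,26,28,2,3.5,0.8,11.4,2.5,7.0,1.7
F,28,30,7,0.8,0.1,2.7,0.4,1.7,0.3
F,30,32,14,1.7,0.2,5.6,0.5,4.1,0.4
F,32,34,22,1.3,0.1,4.3,0.4,3.6,0.4
F,34,36,30,1.5,0.1,4.9,0.4,4.6,0.4
F,36,38,20,1.2,0.1,4.1,0.4,4.3,0.4
F,38,40,5,1.2,0.2,4.4,0.6,4.6,0.7
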