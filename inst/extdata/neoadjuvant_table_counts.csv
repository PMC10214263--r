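endpoint,low_favorable,low_unfavorable,high_favorable,high_unfavorable,favorable_label,unfavorable_label
response,17,8,7,20,CR/PR,SD/PD
trg,12,12,4,22,1a/1b,2/3
ypt,11,13,4,21,T0/T1,T2/T3
ypn,18,6,8,17,N0,N1-N3
yptnm,13,12,4,23,pCR/I,II/III
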