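junction,imp_0_2kN,imp_2_4kN,total
1,160,105,265
2,155,95,250
3,160,125,285
4,173,100,273
5,160,105,265
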