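element,slope,blank_1,blank_2,blank_3
Ca,1,0.00946000000000,0.01,0.0105400000000
Mg,1,0.00925000000000,0.01,0.0107500000000
Mn,1,0.00985433333333,0.01,0.0101456666667
Na,1,0.00603333333333,0.01,0.0139666666667
As,1,0.00972800000000,0.01,0.0102720000000
Cr,1,0.00957333333333,0.01,0.0104266666667
Pb,1,0.00903333333333,0.01,0.0109666666667
Zn,1,0.00964666666667,0.01,0.0103533333333
Cd,1,0.00998743333333,0.01,0.0100125666667
Cu,1,0.00925333333333,0.01,0.0107466666667
K,1,0.00781666666667,0.01,0.0121833333333
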