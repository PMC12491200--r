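sample_id,element,replicate,concentration
A,Cr,1,4.015e-03
A,Cr,2,4.770e-03
A,Cr,3,5.525e-03
A,Cu,1,4.914e-02
A,Cu,2,5.610e-02
A,Cu,3,6.306e-02
A,Pb,1,1.813e-02
A,Pb,2,1.960e-02
A,Pb,3,2.107e-02
A,Zn,1,6.471e-02
A,Zn,2,6.630e-02
A,Zn,3,6.789e-02
A,As,1,2.37e-03
A,As,2,3.92e-03
A,As,3,5.47e-03
A,Cd,1,1.752e-03
A,Cd,2,2.740e-03
A,Cd,3,3.728e-03
A,Ca,1,2.3219e+02
A,Ca,2,2.3600e+02
A,Ca,3,2.3981e+02
A,K,1,2.2454e+01
A,K,2,2.2600e+01
A,K,3,2.2746e+01
A,Mg,1,2.78107e+01
A,Mg,2,2.79000e+01
A,Mg,3,2.79893e+01
A,Na,1,5.0387e+01
A,Na,2,5.0700e+01
A,Na,3,5.1013e+01
A,Mn,1,1.371e-02
A,Mn,2,1.490e-02
A,Mn,3,1.609e-02
B,Cr,1,3.377e-03
B,Cr,2,3.740e-03
B,Cr,3,4.103e-03
B,Cu,1,3.9602e-01
B,Cu,2,4.0500e-01
B,Cu,3,4.1398e-01
B,Pb,1,2.197e-02
B,Pb,2,2.340e-02
B,Pb,3,2.483e-02
B,Zn,1,2.429637e+01
B,Zn,2,2.430000e+01
B,Zn,3,2.430363e+01
B,As,1,ND
B,As,2,ND
B,As,3,ND
B,Cd,1,ND
B,Cd,2,ND
B,Cd,3,ND
B,Ca,1,1.45066e+02
B,Ca,2,1.46000e+02
B,Ca,3,1.46934e+02
B,K,1,1.2996e+01
B,K,2,1.3100e+01
B,K,3,1.3204e+01
B,Mg,1,2.06848e+01
B,Mg,2,2.07000e+01
B,Mg,3,2.07152e+01
B,Na,1,3.3372e+01
B,Na,2,3.3600e+01
B,Na,3,3.3828e+01
B,Mn,1,1.0725e-02
B,Mn,2,1.1100e-02
B,Mn,3,1.1475e-02
C,Cr,1,1.777e-03
C,Cr,2,2.360e-03
C,Cr,3,2.943e-03
C,Cu,1,1.689e-02
C,Cu,2,1.930e-02
C,Cu,3,2.171e-02
C,Pb,1,1.037e-02
C,Pb,2,1.090e-02
C,Pb,3,1.143e-02
C,Zn,1,6.966e-02
C,Zn,2,7.170e-02
C,Zn,3,7.374e-02
C,As,1,ND
C,As,2,ND
C,As,3,ND
C,Cd,1,6.10e-05
C,Cd,2,1.52e-04
C,Cd,3,2.43e-04
C,Ca,1,4.226e-01
C,Ca,2,4.340e-01
C,Ca,3,4.454e-01
C,K,1,1.1092e+00
C,K,2,1.1300e+00
C,K,3,1.1508e+00
C,Mg,1,1.01e-01
C,Mg,2,1.31e-01
C,Mg,3,1.61e-01
C,Na,1,2.97e-01
C,Na,2,3.08e-01
C,Na,3,3.19e-01
C,Mn,1,1.1482e-02
C,Mn,2,1.1600e-02
C,Mn,3,1.1718e-02
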