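element,rfd,csf,who_limit
As,0.003,1.5,0.3
Cd,0.001,,0.2
Cr,0.02,0.5,0.02
Cu,0.001,,3
Mn,0.14,,2
Pb,0.004,0.0085,10
Zn,0.3,,27.4
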