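name,formula,class,retention_time,abundance_A,abundance_B,abundance_C
2-methylheptane,C8H18,Alkane,3.314,-,28.1,-
2-methylheptane,C8H18,Alkane,3.335,26.3,-,22.5
3-methylheptane,C8H18,Alkane,3.479,-,30.4,-
3-methylheptane,C8H18,Alkane,3.438,29.1,-,-
Octane,C8H18,Alkane,3.767,-,11,-
Octane,C8H18,Alkane,3.788,10.5,-,33.2
Decane,C10H22,Alkane,4.241,-,-,0.42
4-methyl-octane,C9H20,Alkane,5.003,-,6.07,-
4-methyl-octane,C9H20,Alkane,5.004,5.83,-,-
p-xylene,C8H10,Aromatic hydrocarbon,5.23,11.4,11.5,-
p-xylene,C8H10,Aromatic hydrocarbon,5.251,-,-,9.59
Nonane,C9H20,Alkane,5.931,-,3.39,3.31
6-methyl-octadecane,C19H40,Alkane,5.93,3.2,-,-
6-methyl-octadecane,C19H40,Alkane,4.365,-,2.58,-
6-methyl-octadecane,C19H40,Alkane,29.4,-,-,0.64
Undecane,C11H24,Alkane,12.236,-,-,0.6
Dodecane,C12H26,Alkane,15.409,-,-,0.35
"2,6-dimethyl-heptadecane",C19H40,Alkane,21.096,-,-,0.39
Hexadecane,C16H34,Alkane,26.021,-,2.16,0.73
Butyl ester-6-tetradecane-sulfonic acid,C18H38O3S,Ester,29.421,-,-,0.64
"2,4,7,14-Tetramethyl-4-vinyl-tricyclo[5.4.3.0(1,8)]tetradecan-6-ol",C20H34O,Alcohol,33.871,-,-,0.39
"Cholestan-3-ol, 2-methylene-, (3b,5a)",C28H48O,Alcohol,34.49,-,-,0.41
"Methyl ester-11,14-Eicosadienoic acid",C21H38O2,Fatty acid methyl ester,35.767,-,-,0.51
5-methyl-heneicosane,C22H46,Alkane,37.209,-,1.58,0.84
(Z)-5-Methyl-6-heneicosen-11-one,C22H42O,Ketone,39.229,-,-,1.02
Octadecamethyl-cyclononasiloxane,C18H54O9Si9,Cyclosiloxane,39.517,4.04,-,-
(Z)-9-Octadecenamide,C18H35NO,Fatty amide,40.939,5.56,-,-
"3,4',5,6'-tetrakis(1,1-dimethylethyl)-[1,1'-biphenyl]-2,3'-diol",C28H42O2,Phenol,40.98,-,-,1.01
3-ethyl-5-(2-ethylbutyl)-octadecane,C26H54,Alkane,41.413,-,-,2.6
1-Monolinoleoylglycerol trimethylsilyl ether,C27H54O4Si2,Ether,41.825,1.58,-,-
1-Monolinoleoylglycerol trimethylsilyl ether,C27H54O4Si2,Ether,45.348,-,-,0.86
Heptacosane,C27H56,Alkane,43,-,-,0.74
"Oleic acid, 3-(octadecycloxy)propyl ester",C39H76O3,Fatty acid ester,43.535,-,-,1.2
"3',8,8'-Trimethyl-3-piperidyl-2,2'-binaphthalene-1,1',4,4'-tetrone",C31H29N2O4,Quinonoid aromatic compound,43.844,-,-,1.12
"1,1'-[1,3-propanediylbis(oxy)]bis-octadecane",C39H80O2,Alkane,45.987,-,-,0.61
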