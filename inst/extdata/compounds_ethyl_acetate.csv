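name,formula,class,retention_time,abundance_A,abundance_B,abundance_C
"Cis-1,3-dimethylcyclohexane",C8H16,Cyclic alkane,3.591,6.51,6.07,4.03
Trans-1-ethyl-3-methylcyclopentane,C8H16,Cyclic alkane,3.733,-,-,4.77
Trans-1-ethyl-3-methylcyclopentane,C8H16,Cyclic alkane,3.753,7.47,6.58,-
"Bicyclo[2.1.1]hexan-2-ol, 2-ethenyl",C8H12O,Alcohol,5.307,-,-,0.15
"Benzene propionic acid, 4-tridecyl ester",C22H36O2,Ester,5.892,1.76,-,-
Nonane,C9H20,Alkane,5.932,-,-,1.34
O-decyl-hydroxylamine,C10H23NO,Hydroxylamine derivative,5.932,-,1.64,-
"p,a-dimethyl-phenethylamine",C10H15N,Amine,7.93,-,-,0.17
Decane,C10H22,Alkane,8.959,1.76,-,-
Decane,C10H22,Alkane,8.979,-,5.23,3.91
"N-a,N-w-Di-cbz-L-arginine",C22H26N4O6,Amide,10.291,-,-,0.81
"Carbamothioic acid, O-isopropyl ester",C4H9NOS,Carbamate ester,10.997,-,-,0.18
"3-(4-isopropylphenyl)-1,1-dimethylurea",C12H18N2O,Amide,11.582,-,-,0.17
Undecane,C11H24,Alkane,12.268,7.42,-,-
Undecane,C11H24,Alkane,12.288,-,-,5.25
Undecane,C11H24,Alkane,12.289,-,7.11,-
Dodecane,C12H26,Alkane,15.396,7.06,-,-
Dodecane,C12H26,Alkane,15.416,-,6.66,-
"Oxalic acid, isobutyl nonyl ester",C15H28O4,Ester,15.457,-,-,4.91
2-Aminononadecane,C19H41N,Amine,18.362,-,-,0.27
"Cyclohexasiloxane, dodecamethyl-",C12H36O6Si6,Siloxane,19.129,-,-,0.19
5-Aminovaleric acid,C5H11NO2,Delta-amino acid,20.945,-,-,10.5
Tetradecane,C14H30,Alkane,21.026,14.7,14.3,-
N-methyl-1-octadecanamine,C19H41N,Amine,23.003,-,-,0.31
3-methylheneicosane,C22H46,Alkane,23.629,-,0.78,-
N-2-Hydroxyethylpiperazine-N-3-propanesulfonic acid,C9H20N2O4S,Sulfoalkylpiperazine derivative,23.669,-,-,0.82
"1H-Inden-5-ol, 2,3-dihydro-3-(4-hydroxyphenyl)-1,1,3-trimethyl-",C18H20O2,Polycyclic aromatic alcohol,25.304,-,-,0.53
Hexadecane,C16H34,Alkane,25.99,15.2,-,-
Hexadecane,C16H34,Alkane,26.01,-,-,10.4
Nonadecane,C19H40,Alkane,26.01,-,13.9,-
2-t-Butyl-3-methyl-1-(toluene-4-sulfonyl)imidazolidin-4-one,C15H22N2O3S,Imidazolidinone derivative,26.494,-,-,0.86
Benzophenone,C13H10O,Ketone,26.938,-,2.94,-
Benzophenone,C13H10O,Ketone,26.918,-,-,2.7
"1,3,5,7,9-Pentaethylbicyclo[5.3.1]pentasiloxane",C10H28O6Si5,Organosilicon compound,27.604,-,-,0.98
"N,O-di(trimethylsilyl)-2-Aminophenol",C12H23NOSi2,Phenolic compound,28.189,4.99,-,-
3-methyl-nonadecane,C20H42,Alkane,28.27,-,-,2.61
Etymemazine,C20H26N2S,Amine,28.835,-,-,0.48
Octadecane,C18H38,Alkane,30.409,7.73,6.89,5.21
3-amino-3-oxopropanoic acid,C3H5NO3,Carboxylic acid,31.902,-,-,1.14
"1,2-Benzenedicarboxylic acid, butyl octyl ester",C20H30O4,Carboxylic acid,33.819,5.5,1.34,2.78
Butyl nonyl ester phthalic acid,C21H32O4,Ester,33.859,-,2.88,-
Nonadecane,C19H40,Alkane,34.404,3.63,-,-
"2,3-dihydroxypropyl 2-[(7-chloro-4-quinolinyl)amino]benzoate",C19H17ClN2O4,Ester,38.036,1.47,-,-
O-decylhydroxylamine,C10H23NO,Amine,34.444,-,-,2.33
O-decylhydroxylamine,C10H23NO,Amine,34.445,-,2.81,-
Hexadecanamide,C16H33NO,Amide,37.794,-,-,2.2
Heptacosane,C27H56,Alkane,38.077,-,1.68,-
"Silicic acid, diethyl bis(trimethylsilyl) ester",C10H28O4Si3,Silyl ester,42.153,-,-,1.74
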