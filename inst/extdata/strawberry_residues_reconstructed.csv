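# 2023-2024 strawberry monitoring campaign, 83 samples, 31 active substances.
# Every concentration below is a published residue value (mg/kg). The study
# deposited no per-sample table, so sample assignments are RECONSTRUCTED:
# assignments the study text pins are honored exactly (A5 with 5 residues incl.
# flupyradifurone 0.680; S2 with 3 incl. cyflumetofen 0.627; V1 with 5 incl.
# cyflumetofen 0.735; I4 with 6 incl. spirotetramat 0.340; pyrimethanil 2.000
# in I5; tebufenpyrad 0.133 in D3; fenpyroximate only in M3; lambda-cyhalothrin
# only in A7; 7 residues in D2; tetraconazole with fenhexamid in E5;
# trifloxystrobin always with fluopyram; difenoconazole always with
# fluxapyroxad); the remaining assignments are plausible but synthetic.
# Some rows keep the source tables' mixed-language spellings on purpose.
sample_id,pesticide,concentration_mg_kg
A5,flupyradifurone,0.680
A5,cyflumetofen,0.023
A5,bupirimate,0.054
A5,tetraconazole,0.060
A5,hexythiazox,0.037
S2,cyflumetofen,0.627
S2,bupirimate,0.130
S2,spinosad,0.095
V1,cyflumetofen,0.735
V1,pyrimethanil,0.160
V1,bupirimate,0.170
V1,ethirimol,0.017
V1,penconazole,0.047
I4,spirotetramat,0.340
I4,cyflumetofen,0.130
I4,fluopyram,0.100
I4,trifloxystrobin,0.065
I4,tetraconazole,0.016
I4,boscalid,0.012
D2,bupirimate,0.270
D2,fluxapyroxad,0.018
D2,difenoconazole,0.010
D2,cyflumetofen,0.100
D2,fluopyram,0.013
D2,trifloxystrobin,0.010
D2,emamectin,0.013
E5,Tetraconazolo,0.012
E5,fenhexamid,0.015
I5,Pirimentanil,2.000
D3,Tebufenaprid,0.133
M3,fenpyroximate,0.079
A7,Lambda cialotrina,0.015
F1,trifloxystrobin,0.025
F1,fluopyram,0.031
F2,trifloxystrobin,0.035
F2,fluopyram,0.035
F3,trifloxystrobin,0.066
F3,fluopyram,0.077
F4,trifloxystrobin,0.140
F4,fluopyram,0.116
F5,trifloxystrobin,0.100
F5,fluopyram,0.200
F6,trifloxystrobin,0.013
F6,fluopyram,0.012
G1,Difenconazolo,0.250
G1,fluxapyroxad,0.030
G2,difenoconazole,0.220
G2,fluxapyroxad,0.200
G3,difenoconazole,0.026
G3,fluxapyroxad,0.480
G4,difenoconazole,0.070
G4,fluxapyroxad,0.500
C1,cyflumetofen,0.012
C2,cyflumetofen,0.013
C3,cyflumetofen,0.011
C4,cyflumetofen,0.063
C5,cyflumetofen,0.224
C6,cyflumetofen,0.070
C7,cyflumetofen,0.024
B1,Bifenazato,0.083
B2,bifenazate,0.080
B3,bifenazate,0.072
B4,bifenazate,0.012
B5,bifenazate,0.050
H1,bupirimate,0.055
H1,tetraconazole,0.118
H1,fenhexamid,0.170
H1,pirimicarb,0.220
H2,bupirimate,0.062
H2,boscalid,0.080
H2,spinosad,0.012
H3,Bupirimato,0.350
H3,pyrimethanil,1.200
H3,Hexithiazox,0.075
H4,bupirimate,0.012
H4,Etirimol,0.020
H5,bupirimate,0.220
H5,tetraconazole,0.100
H5,acetamiprid,0.012
H6,bupirimate,0.075
H6,spinetoram,0.051
H7,bupirimate,0.096
H7,Penconazolo,0.022
H7,Emamectina,0.010
H8,bupirimate,0.014
H8,hexythiazox,0.050
L1,spinosad,0.086
L1,cyflumetofen,0.034
L2,spinosad,0.015
L2,pyrimethanil,0.350
L2,boscalid,0.130
L3,spinosad,0.011
L3,Clorantraniliprolo,0.010
L4,spinosad,0.018
L4,hexythiazox,0.020
L5,chlorantraniliprole,0.012
L5,emamectin,0.035
L6,flupyradifurone,0.020
L6,acetamiprid,0.033
L6,cyflumetofen,0.256
L7,flupyradifurone,0.060
L7,tetraconazole,0.025
N1,fluxapyroxad,0.650
N1,penthiopyrad,0.226
N2,fluxapyroxad,0.110
N2,hexythiazox,0.010
N3,fluxapyroxad,0.150
N3,fenhexamid,0.051
N4,hexythiazox,0.072
N4,ethirimol,0.010
N5,hexythiazox,0.034
N5,pyrimethanil,0.085
N6,hexythiazox,0.012
N6,cyflumetofen,0.014
P1,cyflufenamid,0.015
P2,penconazole,0.052
P2,fenhexamid,0.100
P3,penconazole,0.018
P3,tetraconazole,0.016
P4,cyprodinil,0.260
P5,fludioxonil,0.220
P5,boscalid,0.054
P6,fludioxonil,0.030
P6,ethirimol,0.054
P7,ethirimol,0.040
P7,pyrimethanil,0.011
Q1,fluopyram,0.110
Q1,tebufenpyrad,0.023
Q2,fluopyram,0.014
Q2,tebufenpyrad,0.030
Q3,tebufenpyrad,0.105
Q3,bifenazate,0.026
Q4,bifenazate,0.010
Q4,spirotetramat,0.052
Q5,tetraconazole,0.018
Q5,fenhexamid,0.161
Q5,emamectin,0.031
Q6,tetraconazole,0.013
Q6,boscalid,0.020
Q7,spinetoram,0.017
Q7,pirimicarb,0.090
Q8,spinetoram,0.016
Q8,pirimicarb,0.047
Q9,spinetoram,0.039
Q9,pirimicarb,0.012
R1,Captano,0.030
R2,penthiopyrad,0.021
R2,acetamiprid,0.013
R3,azoxystrobin,0.012
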