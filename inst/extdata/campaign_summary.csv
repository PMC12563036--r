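# Published per-substance summary statistics of the 2023-2024 strawberry
# monitoring campaign (83 samples, 31 active substances): mean, min, max and
# total concentration in mg/kg over the samples with detections.
pesticide,class,mean_mg_kg,min_mg_kg,max_mg_kg,total_mg_kg
hexythiazox,acaricide,0.039,0.010,0.075,0.310
cyflumetofen,acaricide,0.112,0.011,0.735,2.803
tebufenpyrad,acaricide,0.073,0.023,0.133,0.291
bifenazate,acaricide,0.040,0.010,0.083,0.357
fenpyroximate,acaricide,0.079,0.079,0.079,0.079
bupirimate,fungicide,0.126,0.012,0.350,1.508
fluxapyroxad,fungicide,0.267,0.018,0.650,2.138
difenoconazole,fungicide,0.115,0.010,0.250,0.576
cyflufenamid,fungicide,0.015,0.015,0.015,0.030
penconazole,fungicide,0.035,0.018,0.052,0.139
cyprodinil,fungicide,0.260,0.260,0.260,0.260
fludioxonil,fungicide,0.125,0.030,0.220,0.250
ethirimol,fungicide,0.025,0.010,0.054,0.151
pyrimethanil,fungicide,0.634,0.011,2.000,3.806
fluopyram,fungicide,0.065,0.012,0.200,0.720
trifloxystrobin,fungicide,0.052,0.010,0.140,0.464
tetraconazole,fungicide,0.034,0.012,0.118,0.437
boscalid,fungicide,0.059,0.012,0.130,0.296
fenhexamid,fungicide,0.099,0.015,0.170,0.497
captan,fungicide,0.030,0.030,0.030,0.030
penthiopyrad,fungicide,0.124,0.021,0.226,0.247
azoxystrobin,fungicide,0.012,0.012,0.012,0.012
spinosad,insecticide,0.030,0.011,0.095,0.273
chlorantraniliprole,insecticide,0.011,0.010,0.012,0.034
flupyradifurone,insecticide,0.195,0.020,0.680,0.780
lambda-cyhalothrin,insecticide,0.015,0.015,0.015,0.015
spirotetramat,insecticide,0.196,0.052,0.340,0.392
spinetoram,insecticide,0.032,0.016,0.051,0.162
pirimicarb,insecticide,0.092,0.012,0.220,0.369
emamectin,insecticide,0.022,0.010,0.035,0.133
acetamiprid,insecticide,0.019,0.012,0.033,0.058
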