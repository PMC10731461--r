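# by2growth 0.1.0
# seed: 0
# written: 2026-10-01T00:00:00
# model: improved
parameter,value,min,max
kd,0.000544,0,0.01
mum,0.162,0,10
mumA,0.578,0,10
mumP,2.1e-05,0,10
KS,72.53,0,100
KIS,100,0,100
KA,0.221,0,1
KIA,0.221,0,1
KN,0.835,0,5
KIN,1,0,5
KF,1.108,0,30
KIF,1.404,0,30
KG,18,0,30
KIG,18,0,30
alpha,0.396,0,1
muA,0.0069,0,1
muN,0.0171,0,1
muF,0.0834,0,1
muG,0.273,0,1
muP,0.0268,0,1
deltaA,0.037884,NA,NA
deltaP,0.0256419,NA,NA
mSF,0.526,NA,NA
mSG,0.526,NA,NA
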