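# by2growth 0.1.0
# seed: 0
# written: 2026-10-01T00:00:00
# model: initial
parameter,value,min,max
kd,0.000662,0,0.1
mum,9.47,0,10
KS,17.64,0,100
KIS,17.64,0,100
KA,0.796,0,1
KIA,0.797,0,1
KN,0.133,0,5
KIN,0.135,0,5
muS,0.2235,0,1
muA,0.004863,0,1
muN,0.03013,0,1
muP,0.02883,0,1
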