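state,value
Vm,-0.070
Ca_SR,0.32
Cai,0.0002
d,0.0
f1,1.0
f2,1.0
fCa,1.0
Xr1,0.0
Xr2,1.0
Xs,0.0
h,0.75
j,0.75
m,0.0
Xf,0.1
q,1.0
r,0.0
Nai,9.2
mL,0.0
hL,0.75
RyRa,0.3
RyRo,0.9
RyRc,0.1
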