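state,value
Vm,-0.074996777424920932
Ca_SR,0.11065999902943736
Cai,9.6105281802926794e-06
d,8.1583797977075634e-05
f1,0.58067334947692095
f2,0.99981084174185242
fCa,0.99941609464886294
Xr1,0.49614344244235314
Xr2,0.43534243902761904
Xs,0.031197440324310637
h,0.78995889217449633
j,0.34581373721338632
m,0.03864234134508851
Xf,0.037917364708597509
q,0.84233042277168368
r,0.0055480796420958964
Nai,7.0062796213031939
mL,0.0022224713251661542
hL,0.05470905702742887
RyRa,0.031444213146493802
RyRo,2.1653157850999979e-05
RyRc,0.41960229030568641
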