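state,value
Vm,-0.075021597930161207
Ca_SR,0.12616911435752293
Cai,1.7841055466881987e-05
d,8.1292823540576303e-05
f1,0.87745177394181639
f2,0.99998558516045277
fCa,0.99893477291220423
Xr1,0.13536562733856392
Xr2,0.43546951818409385
Xs,0.031108181062732422
h,0.79080352743966598
j,0.62879636904266112
m,0.038560094127189116
Xf,0.096733707191198073
q,0.8445648279226573
r,0.0055386999686631621
Nai,8.8211905457732538
mL,0.0022120389356754993
hL,0.10225781296866815
RyRa,0.03747010216548647
RyRo,4.4852685836626738e-05
RyRc,0.71399481073399151
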