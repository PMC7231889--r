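# Synthetic reconstruction: diltiazem, an L-type Ca2+ channel blocker with
# weak hERG and Na+ block. The top dose D4 = 10 uM is the printed anchor.
name: diltiazem
provenance: synthetic
channels:
  I_CaL: {ic50_um: 0.76, hill: 0.7}
  I_Kr:  {ic50_um: 13.2, hill: 0.9}
  I_Na:  {ic50_um: 22.4, hill: 0.7}
doses_um: [0.3, 1.0, 3.0, 10.0]
eftpc_max_um: 0.13
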