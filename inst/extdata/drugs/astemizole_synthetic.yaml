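# Synthetic reconstruction: astemizole, a potent hERG blocker with weak
# L-type Ca2+ and Na+ block. The top dose D4 = 0.1 uM is the printed anchor.
name: astemizole
provenance: synthetic
channels:
  I_Kr:  {ic50_um: 0.0077, hill: 0.9}
  I_CaL: {ic50_um: 1.1, hill: 1.0}
  I_Na:  {ic50_um: 3.4, hill: 1.0}
doses_um: [0.003, 0.01, 0.03, 0.1]
eftpc_max_um: 0.00026
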