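# Synthetic reconstruction of the bepridil block table (multichannel blocker:
# potent hERG block plus L-type Ca2+, peak and late Na+ block). IC50/hill
# chosen so that 10 uM leaves exactly 32% residual I_CaL, the printed anchor;
# remaining values are literature-typical patch-clamp estimates.
name: bepridil
provenance: synthetic
channels:
  I_Kr:  {ic50_um: 0.149, hill: 0.9}
  I_CaL: {ic50_um: 3.074, hill: 0.639}
  I_Na:  {ic50_um: 2.929, hill: 1.16}
  I_NaL: {ic50_um: 1.814, hill: 1.4}
doses_um: [0.3, 1.0, 3.0, 10.0]
eftpc_max_um: 0.033
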