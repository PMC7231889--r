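# Synthetic reconstruction: dofetilide as a selective rapid delayed-rectifier
# (hERG) blocker. The top in vitro dose D4 blocks ~80% of I_Kr; doses D5-D7
# (ad hoc extensions) are 10x/30x/100x EFTPC_max.
name: dofetilide
provenance: synthetic
channels:
  I_Kr: {ic50_um: 0.0049, hill: 0.9}
doses_um: [0.0024, 0.006, 0.012, 0.020]
eftpc_max_um: 0.0024
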