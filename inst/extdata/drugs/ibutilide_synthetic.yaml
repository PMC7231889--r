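# Synthetic reconstruction: ibutilide as a selective hERG blocker (class III).
name: ibutilide
provenance: synthetic
channels:
  I_Kr: {ic50_um: 0.02, hill: 0.9}
doses_um: [0.01, 0.03, 0.06, 0.10]
eftpc_max_um: 0.014
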