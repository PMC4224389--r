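format-version: 1.4
ontology: anatomy_t

[Term]
id: TA:0000001
name: heart

[Term]
id: TA:0000002
name: heart muscle

[Term]
id: TA:0000003
name: NK cell (activated)

[Term]
id: TA:0000004
name: valve of aorta
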