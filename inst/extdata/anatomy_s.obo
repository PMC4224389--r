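format-version: 1.4
ontology: anatomy_s

[Term]
id: SA:0000001
name: heart
synonym: "cardiac organ" EXACT []

[Term]
id: SA:0000002
name: cardiac muscle
synonym: "musculus cordis" RELATED []

[Term]
id: SA:0000003
name: NK-cell,  activated

[Term]
id: SA:0000004
name: aorta wall

[Term]
id: SA:0000005
name: embryonic heart
is_obsolete: true
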