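format-version: 1.4
ontology: bk_cardio

[Term]
id: BKC:0000001
name: heart muscle
synonym: "cardiac muscle" EXACT []
synonym: "musculus cordis" RELATED []

[Term]
id: BKC:0000002
name: pericardial sac
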