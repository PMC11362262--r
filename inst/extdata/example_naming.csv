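participant_id,object_id,seen_before,concepts
p001,1,no,rainbow
p001,2,yes,house
p002,1,no,rainbow;prism
p002,2,yes,house
p003,1,no,arch
p003,2,no,hut
p004,1,yes,rainbow
p004,2,yes,house
p005,1,no,
p005,2,no,half circle
p006,1,no,curve
p006,2,yes,house
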