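variant,canonical
half circle,semicircle
semi-circle,semicircle
hut,house
cabin,house
arch,curve
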