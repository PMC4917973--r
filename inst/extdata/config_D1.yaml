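# 20-fish group, strong indoor lighting
profile: D1
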