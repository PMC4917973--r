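# matched to the built-in renderer (fish length 60 px, head half-width 8)
profile: synthetic
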