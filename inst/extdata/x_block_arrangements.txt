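>reference_species X
1 2 3 4 5
>target_species X1
1 -4 3 -2 5
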