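br_id	ingroup	gene_a	gene_b	state
I	A	brI_left	brI_right	adjacent_same_order
I	B	brI_left	brIV_distal	adjacent_same_order
II	A	brII_left	brII_right	adjacent_same_order
II	B	brII_left	brV_distal	adjacent_same_order
III	A	brIII_left	brIII_right	adjacent_same_order
III	B	brIII_left	brI_distal	adjacent_same_order
IV	A	brIV_left	brIV_right	adjacent_same_order
IV	B	brIV_left	brII_distal	adjacent_same_order
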