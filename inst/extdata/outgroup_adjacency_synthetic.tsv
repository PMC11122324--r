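br_id	species	gene_a	gene_b	state
I	outgroup_basal_1	brI_left	brI_right	adjacent_same_order
I	outgroup_basal_2	brI_left	brI_right	adjacent_same_order
I	outgroup_asian	brI_left	brI_right	adjacent_same_order
I	outgroup_culicine_1	brI_left	brI_right	unresolved
I	outgroup_culicine_2	brI_left	brI_right	not_adjacent
II	outgroup_basal_1	brII_left	brII_right	adjacent_same_order
II	outgroup_basal_2	brII_left	brV_distal	adjacent_same_order
II	outgroup_asian	brII_left	brII_right	unresolved
II	outgroup_culicine_1	brII_left	brII_right	unresolved
II	outgroup_culicine_2	brII_left	brII_right	unresolved
III	outgroup_basal_1	brIII_left	brIII_right	adjacent_same_order
III	outgroup_basal_2	brIII_left	brIII_right	adjacent_same_order
III	outgroup_asian	brIII_left	brIII_right	adjacent_same_order
III	outgroup_culicine_1	brIII_left	brIII_right	adjacent_same_order
III	outgroup_culicine_2	brIII_left	brIII_right	adjacent_same_order
IV	outgroup_basal_1	brIV_left	brIV_right	adjacent_same_order
IV	outgroup_basal_2	brIV_left	brIV_right	adjacent_same_order
IV	outgroup_asian	brIV_left	brIV_right	not_adjacent
IV	outgroup_culicine_1	brIV_left	brIV_right	unresolved
IV	outgroup_culicine_2	brIV_left	brIV_right	unresolved
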