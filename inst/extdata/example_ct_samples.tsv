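sample	species	subset	replicate
mouse_MaSCbasal_1	mouse	MaSC/basal	1
mouse_MaSCbasal_2	mouse	MaSC/basal	2
mouse_MaSCbasal_3	mouse	MaSC/basal	3
mouse_MaSCbasal_4	mouse	MaSC/basal	4
mouse_LP_1	mouse	LP	1
mouse_LP_2	mouse	LP	2
mouse_LP_3	mouse	LP	3
mouse_LP_4	mouse	LP	4
mouse_ML_1	mouse	ML	1
mouse_ML_2	mouse	ML	2
mouse_ML_3	mouse	ML	3
mouse_ML_4	mouse	ML	4
mouse_stroma_1	mouse	stroma	1
mouse_stroma_2	mouse	stroma	2
mouse_stroma_3	mouse	stroma	3
mouse_stroma_4	mouse	stroma	4
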