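# Meta-analytic "mirror system" search-space peaks (action observation AND
# imitation conjunction): cluster peak MNI coordinates (mm) and cluster sizes
# (voxels). Rows 8-9 (SMA) are approximate; the published table is partially
# garbled for those clusters.
cluster_id	cluster_size	x	y	z	label
1	2755	61	3	18	Right BA 44/BA 45
2	229	-54	7	33	Left BA 44 pars opercularis
3	174	53	-65	4	Right MTG/FFG
4	141	-37	-40	50	Left IPL/aSMG
5	130	-50	-70	4	Left MTG
6	109	45	-57	-17	Right FFG/ITG
7	91	-53	-50	9	Left MTG
8	36	0	13	53	Left and right SMA (approx.)
9	33	4	11	52	Right SMA (approx.)
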