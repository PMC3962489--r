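marker_id	arm_label	class	n_scored	n_het	n_loss	n_loss_excl
S2G_pooled_13	NA	S2G	309	309	0	0
S2N_pooled_13	NA	S2N	308	308	0	0
MgSTS_98	1L	BC1N	48	46	2	1
MgSTS_787	2L	BC1N	48	47	1	0
MgSTS_724	6L	BC1N	48	45	3	2
MgSTS_376	7L	BC1N	48	48	0	0
MgSTS_358	11R	BC1N	48	47	1	0
MgSTS_780	11L	BC1N	48	47	1	0
MgSTS_847	1L	BC1N	48	46	2	1
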