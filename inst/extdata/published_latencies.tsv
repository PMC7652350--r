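condition	group	latency_ms	sd_replicates	F_adjusted
Control	DCD	791	5.92	7.19
Control	TD	694	6.96	7.19
Motor	DCD	854	5.78	14.82
Motor	TD	751	2.89	14.82
Spatial	DCD	757	5.66	3.32
Spatial	TD	703	4.31	3.32
Temporal	DCD	578	5.81	NA
Temporal	TD	585	2.73	NA
Visual	DCD	856	3.84	15.30
Visual	TD	774	3.55	15.30
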