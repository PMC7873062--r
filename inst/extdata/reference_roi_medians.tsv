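sample	roi	metric	median	n_voxels
Locust1	AL	FA	0.36	NA
Locust1	CC	FA	0.23	NA
Locust1	Rt	FA	0.67	NA
Locust1	Me	FA	0.49	NA
Locust1	MB	FA	0.36	NA
Locust1	La	FA	0.56	NA
Locust1	MN	FA	0.32	NA
Locust1	Lox	FA	0.44	NA
Locust1	Ax_tk	FA	0.62	NA
Locust1	AL	MD	0.00046	NA
Locust1	CC	MD	0.00076	NA
Locust1	Rt	MD	0.00064	NA
Locust1	Me	MD	0.00035	NA
Locust1	MB	MD	0.00047	NA
Locust1	La	MD	0.00052	NA
Locust1	MN	MD	0.00047	NA
Locust1	Lox	MD	0.00037	NA
Locust1	Ax_tk	MD	0.00046	NA
Locust1	AL	MK	1.88	NA
Locust1	CC	MK	0.73	NA
Locust1	Rt	MK	1.04	NA
Locust1	Me	MK	2.64	NA
Locust1	MB	MK	2.39	NA
Locust1	La	MK	1.6	NA
Locust1	MN	MK	1.69	NA
Locust1	Lox	MK	2.65	NA
Locust1	Ax_tk	MK	2.46	NA
Locust1	AL	KA	0.95	NA
Locust1	CC	KA	0.32	NA
Locust1	Rt	KA	0.89	NA
Locust1	Me	KA	1.64	NA
Locust1	MB	KA	1.57	NA
Locust1	La	KA	0.81	NA
Locust1	MN	KA	0.71	NA
Locust1	Lox	KA	1.07	NA
Locust1	Ax_tk	KA	1.86	NA
Locust2	AL	FA	0.5	NA
Locust2	CC	FA	0.31	NA
Locust2	Rt	FA	0.68	NA
Locust2	Me	FA	0.49	NA
Locust2	MB	FA	0.5	NA
Locust2	La	FA	0.67	NA
Locust2	MN	FA	0.51	NA
Locust2	Lox	FA	0.62	NA
Locust2	Ax_tk	FA	0.67	NA
Locust2	AL	MD	0.00043	NA
Locust2	CC	MD	0.00062	NA
Locust2	Rt	MD	0.00065	NA
Locust2	Me	MD	0.00037	NA
Locust2	MB	MD	0.00036	NA
Locust2	La	MD	0.00045	NA
Locust2	MN	MD	0.00048	NA
Locust2	Lox	MD	0.00026	NA
Locust2	Ax_tk	MD	0.00052	NA
Locust2	AL	MK	2.23	NA
Locust2	CC	MK	0.75	NA
Locust2	Rt	MK	0.9	NA
Locust2	Me	MK	2.51	NA
Locust2	MB	MK	3.52	NA
Locust2	La	MK	2.03	NA
Locust2	MN	MK	2.02	NA
Locust2	Lox	MK	4.6	NA
Locust2	Ax_tk	MK	2.48	NA
Locust2	AL	KA	0.92	NA
Locust2	CC	KA	0.39	NA
Locust2	Rt	KA	0.59	NA
Locust2	Me	KA	1.11	NA
Locust2	MB	KA	2.08	NA
Locust2	La	KA	1.19	NA
Locust2	MN	KA	0.93	NA
Locust2	Lox	KA	3.83	NA
Locust2	Ax_tk	KA	1.6	NA
Locust3	AL	FA	0.39	NA
Locust3	CC	FA	0.28	NA
Locust3	Rt	FA	0.65	NA
Locust3	Me	FA	0.52	NA
Locust3	MB	FA	0.24	NA
Locust3	La	FA	0.71	NA
Locust3	MN	FA	0.28	NA
Locust3	Lox	FA	0.61	NA
Locust3	Ax_tk	FA	0.69	NA
Locust3	AL	MD	0.00059	NA
Locust3	CC	MD	0.00074	NA
Locust3	Rt	MD	0.00057	NA
Locust3	Me	MD	0.00031	NA
Locust3	MB	MD	0.00053	NA
Locust3	La	MD	0.00041	NA
Locust3	MN	MD	0.00051	NA
Locust3	Lox	MD	0.00028	NA
Locust3	Ax_tk	MD	0.00042	NA
Locust3	AL	MK	2.24	NA
Locust3	CC	MK	0.85	NA
Locust3	Rt	MK	0.89	NA
Locust3	Me	MK	2.04	NA
Locust3	MB	MK	1.94	NA
Locust3	La	MK	1.84	NA
Locust3	MN	MK	1.77	NA
Locust3	Lox	MK	4.91	NA
Locust3	Ax_tk	MK	2.65	NA
Locust3	AL	KA	0.48	NA
Locust3	CC	KA	0.36	NA
Locust3	Rt	KA	0.65	NA
Locust3	Me	KA	1.04	NA
Locust3	MB	KA	0.41	NA
Locust3	La	KA	1.55	NA
Locust3	MN	KA	0.45	NA
Locust3	Lox	KA	4.54	NA
Locust3	Ax_tk	KA	2.22	NA
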