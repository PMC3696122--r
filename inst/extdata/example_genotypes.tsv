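subject_id	phenotype	TaqIA	TaqIB	DRD4_521	DRD4_615
S00001	1	C/C	G/G	C/T	A/A
S00002	1	C/C	G/G	C/T	A/G
S00003	1	T/T	A/G	T/T	A/A
S00004	1	C/T	A/G	T/T	A/A
S00005	1	C/C	G/G	C/T	A/A
S00006	1	C/T	A/G	C/T	./.
S00007	1	C/T	A/G	C/T	A/A
S00008	1	C/C	G/G	C/T	A/G
S00009	1	C/C	G/G	T/T	A/G
S00010	1	C/C	G/G	C/T	A/A
S00011	1	C/T	G/G	C/T	A/A
S00012	1	C/C	./.	./.	A/G
S00013	1	C/C	G/G	C/T	A/G
S00014	1	C/C	G/G	C/T	A/A
S00015	1	C/T	A/G	C/T	A/A
S00016	1	T/T	A/A	T/T	A/A
S00017	1	./.	G/G	T/T	G/G
S00018	1	C/T	A/G	C/T	A/A
S00019	1	C/T	A/G	C/C	A/A
S00020	1	C/T	./.	C/T	A/A
S00021	1	C/T	A/G	C/T	./.
S00022	1	C/C	G/G	T/T	A/A
S00023	1	C/C	G/G	T/T	A/A
S00024	1	C/C	G/G	C/T	A/A
S00025	1	C/T	A/G	C/T	A/G
S00026	0	C/T	A/G	C/T	A/A
S00027	0	C/C	G/G	C/C	A/A
S00028	0	C/C	G/G	T/T	A/A
S00029	0	C/C	G/G	C/T	A/A
S00030	0	C/C	G/G	C/C	A/A
S00031	0	C/C	G/G	T/T	A/A
S00032	0	C/C	G/G	C/T	A/A
S00033	0	C/T	A/G	T/T	A/A
S00034	0	C/C	G/G	C/T	A/G
S00035	0	C/T	A/G	T/T	A/A
S00036	0	C/C	G/G	C/C	A/A
S00037	0	C/C	G/G	C/T	A/A
S00038	0	C/C	G/G	C/T	A/A
S00039	0	C/C	G/G	C/C	A/A
S00040	0	C/C	G/G	C/C	A/A
S00041	0	C/T	A/G	C/C	A/A
S00042	0	C/C	G/G	C/C	A/A
S00043	0	C/C	G/G	T/T	A/G
S00044	0	C/C	G/G	T/T	A/G
S00045	0	C/C	G/G	T/T	A/A
S00046	0	C/C	G/G	T/T	A/A
S00047	0	C/C	G/G	C/T	A/A
S00048	0	C/C	G/G	C/C	A/A
S00049	0	C/T	G/G	C/T	A/A
S00050	0	C/C	G/G	C/C	A/G
S00051	0	C/C	G/G	C/T	A/A
S00052	0	C/C	G/G	C/T	A/A
S00053	0	C/C	G/G	C/T	A/A
S00054	0	C/C	G/G	C/T	A/A
S00055	0	C/T	A/G	C/T	A/A
S00056	0	C/C	G/G	T/T	A/G
S00057	0	C/T	A/G	C/T	A/A
S00058	0	C/C	G/G	C/T	A/A
S00059	0	C/C	G/G	C/C	A/G
S00060	0	C/C	G/G	C/T	A/A
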