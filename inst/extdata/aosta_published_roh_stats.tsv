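breed	tot_roh	min_count	max_count	mean_count	min_length_bp	max_length_bp	mean_length_bp	l_roh_min_mb	l_roh_max_mb
CAS	14921	4	86	50	1000152	39512804	2872455	6.10	381.55
VBP	6875	10	78	45	1002352	55392599	2931795	19.02	403.27
VRP	14604	4	90	53	1000089	71168012	3149324	7.31	557.46
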