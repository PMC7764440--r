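breed	mean_obs_hom	mean_exp_hom	f_min	f_max	f_mean	f_roh_min	f_roh_max	f_roh_mean
CAS	56657.4	56741.8	-0.096	0.104	-0.003	0.002	0.153	0.058
VBP	56562.7	56823.4	-0.089	0.105	-0.010	0.008	0.162	0.053
VRP	56943.6	57025.9	-0.096	0.153	-0.003	0.003	0.224	0.067
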