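snp_id	position	freq_all	freq_nfe	founder_state
rs3729986	chr11:47350047	0.08740	0.1007	present
rs3218719	chr11:47350027	0.02924	0.03450	absent
rs11570050	chr11:47349933	0.6900	0.7171	present
rs3729989	chr11:47348490	0.1178	0.1328	absent
rs11570058	chr11:47347892	0.1138	0.1290	absent
rs1052373	chr11:47333236	0.3519	0.3187	absent
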