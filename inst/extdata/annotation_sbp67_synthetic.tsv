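variant_id	vasc_class	sbp_increasing_allele	trait_memberships	dbp_discordant
rsSBP0001	unlikely related	A	SBP	FALSE
rsSBP0002	vasculature-related	T	SBP	FALSE
rsSBP0003	unknown	G	SBP	FALSE
rsSBP0004	unlikely related	A	SBP	FALSE
rsSBP0005	unlikely related	C	SBP	FALSE
rsSBP0006	unknown	G	SBP	FALSE
rsSBP0007	vasculature-related	T	SBP	FALSE
rsSBP0008	vasculature-related	A	SBP	FALSE
rsSBP0009	vasculature-related	G	SBP	FALSE
rsSBP0010	vasculature-related	A	SBP	FALSE
rsSBP0011	unlikely related	T	SBP	FALSE
rsSBP0012	unlikely related	A	SBP	FALSE
rsSBP0013	unlikely related	G	SBP	FALSE
rsSBP0014	unlikely related	G	SBP	FALSE
rsSBP0015	unlikely related	A	SBP	FALSE
rsSBP0016	unlikely related	G	SBP	FALSE
rsSBP0017	vasculature-related	C	SBP	FALSE
rsSBP0018	unknown	C	SBP	FALSE
rsSBP0019	unlikely related	A	SBP	FALSE
rsSBP0020	unlikely related	A	SBP	FALSE
rsSBP0021	unlikely related	G	SBP	FALSE
rsSBP0022	unknown	G	SBP	FALSE
rsSBP0023	unlikely related	T	SBP	FALSE
rsSBP0024	vasculature-related	G	SBP	FALSE
rsSBP0025	unlikely related	G	SBP	FALSE
rsSBP0026	unlikely related	A	SBP	FALSE
rsSBP0027	vasculature-related	G	SBP	FALSE
rsSBP0028	vasculature-related	A	SBP	FALSE
rsSBP0029	unknown	A	SBP	FALSE
rsSBP0030	unlikely related	G	SBP	FALSE
rsSBP0031	vasculature-related	A	SBP	FALSE
rsSBP0032	unlikely related	A	SBP	FALSE
rsSBP0033	unlikely related	G	SBP	FALSE
rsSBP0034	vasculature-related	C	SBP	FALSE
rsSBP0035	vasculature-related	T	SBP	FALSE
rsSBP0036	vasculature-related	T	SBP	FALSE
rsSBP0037	vasculature-related	G	SBP	FALSE
rsSBP0038	unknown	G	SBP	FALSE
rsSBP0039	vasculature-related	T	SBP	FALSE
rsSBP0040	unlikely related	C	SBP	FALSE
rsSBP0041	unknown	C	SBP	FALSE
rsSBP0042	unknown	C	SBP	FALSE
rsSBP0043	unlikely related	G	SBP	FALSE
rsSBP0044	vasculature-related	A	SBP	FALSE
rsSBP0045	unlikely related	T	SBP	FALSE
rsSBP0046	unlikely related	C	SBP	FALSE
rsSBP0047	vasculature-related	C	SBP	FALSE
rsSBP0048	unknown	T	SBP	FALSE
rsSBP0049	unlikely related	A	SBP	FALSE
rsSBP0050	unlikely related	T	SBP	FALSE
rsSBP0051	unknown	A	SBP	FALSE
rsSBP0052	unlikely related	G	SBP	FALSE
rsSBP0053	unknown	A	SBP	FALSE
rsSBP0054	unlikely related	C	SBP	FALSE
rsSBP0055	unlikely related	G	SBP	FALSE
rsSBP0056	vasculature-related	T	SBP	FALSE
rsSBP0057	unknown	G	SBP	FALSE
rsSBP0058	unlikely related	C	SBP	FALSE
rsSBP0059	unknown	T	SBP	FALSE
rsSBP0060	unknown	C	SBP	FALSE
rsSBP0061	unlikely related	G	SBP	FALSE
rsSBP0062	unknown	A	SBP	FALSE
rsSBP0063	unlikely related	A	SBP	FALSE
rsSBP0064	vasculature-related	G	SBP	FALSE
rsSBP0065	vasculature-related	G	SBP	FALSE
rsSBP0066	vasculature-related	G	SBP	FALSE
rsSBP0067	unknown	A	SBP	FALSE
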