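variant_id	vasc_class	sbp_increasing_allele	trait_memberships	dbp_discordant
rsBP0001	unknown	T	SBP,PP,MAP,DBP	FALSE
rsBP0002	vasculature-related	T	MAP	FALSE
rsBP0003	unlikely related	G	PP,DBP,SBP,MAP	FALSE
rsBP0004	unlikely related	A	DBP,SBP	FALSE
rsBP0005	unlikely related	C	SBP	FALSE
rsBP0006	unknown	T	SBP,MAP,DBP	FALSE
rsBP0007	unknown	T	PP,MAP	TRUE
rsBP0008	unlikely related	T	SBP,MAP,DBP	FALSE
rsBP0009	vasculature-related	C	DBP,SBP,PP	FALSE
rsBP0010	unknown	C	MAP	FALSE
rsBP0011	unknown	A	PP,SBP,MAP	TRUE
rsBP0012	vasculature-related	A	MAP,DBP,SBP,PP	FALSE
rsBP0013	unknown	T	PP,SBP	TRUE
rsBP0014	vasculature-related	T	MAP,SBP,DBP	FALSE
rsBP0015	vasculature-related	T	DBP,MAP,PP,SBP	FALSE
rsBP0016	unlikely related	A	DBP,PP	FALSE
rsBP0017	unlikely related	A	PP,SBP,MAP	TRUE
rsBP0018	unknown	A	SBP,PP	FALSE
rsBP0019	vasculature-related	A	PP	FALSE
rsBP0020	vasculature-related	A	SBP	FALSE
rsBP0021	unknown	G	MAP	FALSE
rsBP0022	unknown	A	SBP,PP,DBP	FALSE
rsBP0023	unknown	T	MAP,SBP	FALSE
rsBP0024	vasculature-related	A	MAP,DBP	FALSE
rsBP0025	unlikely related	C	SBP,PP,DBP	FALSE
rsBP0026	unlikely related	G	MAP	FALSE
rsBP0027	vasculature-related	T	PP	FALSE
rsBP0028	vasculature-related	G	SBP	FALSE
rsBP0029	vasculature-related	A	PP,SBP,MAP	TRUE
rsBP0030	vasculature-related	T	DBP,SBP,MAP	FALSE
rsBP0031	unknown	A	MAP,DBP,PP	FALSE
rsBP0032	vasculature-related	G	PP	TRUE
rsBP0033	unlikely related	C	DBP,PP,SBP	FALSE
rsBP0034	vasculature-related	T	PP,MAP	FALSE
rsBP0035	unlikely related	T	PP,SBP	FALSE
rsBP0036	vasculature-related	C	MAP	FALSE
rsBP0037	vasculature-related	A	MAP,SBP,DBP,PP	FALSE
rsBP0038	vasculature-related	G	MAP,SBP,DBP	FALSE
rsBP0039	vasculature-related	A	PP,SBP	TRUE
rsBP0040	unlikely related	T	PP,MAP,SBP,DBP	FALSE
rsBP0041	unlikely related	C	PP	FALSE
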