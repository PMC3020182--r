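probeset_id	class	transcript	position	revision
ENDO_SYN_0001_at	endogenous	hk001	none	none
ENDO_SYN_0002_at	endogenous	hk002	none	none
ENDO_SYN_0003_at	endogenous	hk003	none	none
ENDO_SYN_0004_at	endogenous	hk004	none	none
ENDO_SYN_0005_at	endogenous	hk005	none	none
ENDO_SYN_0006_at	endogenous	hk006	none	none
ENDO_SYN_0007_at	endogenous	hk007	none	none
ENDO_SYN_0008_at	endogenous	hk008	none	none
ENDO_SYN_0009_at	endogenous	hk009	none	none
ENDO_SYN_0010_at	endogenous	hk010	none	none
ENDO_SYN_0011_at	endogenous	hk011	none	none
ENDO_SYN_0012_at	endogenous	hk012	none	none
ENDO_SYN_0013_at	endogenous	hk013	none	none
ENDO_SYN_0014_at	endogenous	hk014	none	none
ENDO_SYN_0015_at	endogenous	hk015	none	none
ENDO_SYN_0016_at	endogenous	hk016	none	none
ENDO_SYN_0017_at	endogenous	hk017	none	none
ENDO_SYN_0018_at	endogenous	hk018	none	none
ENDO_SYN_0019_at	endogenous	hk019	none	none
ENDO_SYN_0020_at	endogenous	hk020	none	none
ENDO_SYN_0021_at	endogenous	hk021	none	none
ENDO_SYN_0022_at	endogenous	hk022	none	none
ENDO_SYN_0023_at	endogenous	hk023	none	none
ENDO_SYN_0024_at	endogenous	hk024	none	none
ENDO_SYN_0025_at	endogenous	hk025	none	none
ENDO_SYN_0026_at	endogenous	hk026	none	none
ENDO_SYN_0027_at	endogenous	hk027	none	none
ENDO_SYN_0028_at	endogenous	hk028	none	none
ENDO_SYN_0029_at	endogenous	hk029	none	none
ENDO_SYN_0030_at	endogenous	hk030	none	none
ENDO_SYN_0031_at	endogenous	hk031	none	none
ENDO_SYN_0032_at	endogenous	hk032	none	none
ENDO_SYN_0033_at	endogenous	hk033	none	none
ENDO_SYN_0034_at	endogenous	hk034	none	none
ENDO_SYN_0035_at	endogenous	hk035	none	none
ENDO_SYN_0036_at	endogenous	hk036	none	none
ENDO_SYN_0037_at	endogenous	hk037	none	none
ENDO_SYN_0038_at	endogenous	hk038	none	none
ENDO_SYN_0039_at	endogenous	hk039	none	none
ENDO_SYN_0040_at	endogenous	hk040	none	none
ENDO_SYN_0041_at	endogenous	hk041	none	none
ENDO_SYN_0042_at	endogenous	hk042	none	none
ENDO_SYN_0043_at	endogenous	hk043	none	none
ENDO_SYN_0044_at	endogenous	hk044	none	none
ENDO_SYN_0045_at	endogenous	hk045	none	none
ENDO_SYN_0046_at	endogenous	hk046	none	none
ENDO_SYN_0047_at	endogenous	hk047	none	none
ENDO_SYN_0048_at	endogenous	hk048	none	none
ENDO_SYN_0049_at	endogenous	hk049	none	none
ENDO_SYN_0050_at	endogenous	hk050	none	none
ENDO_SYN_0051_at	endogenous	hk051	none	none
ENDO_SYN_0052_at	endogenous	hk052	none	none
ENDO_SYN_0053_at	endogenous	hk053	none	none
ENDO_SYN_0054_at	endogenous	hk054	none	none
ENDO_SYN_0055_at	endogenous	hk055	none	none
ENDO_SYN_0056_at	endogenous	hk056	none	none
ENDO_SYN_0057_at	endogenous	hk057	none	none
ENDO_SYN_0058_at	endogenous	hk058	none	none
ENDO_SYN_0059_at	endogenous	hk059	none	none
ENDO_SYN_0060_at	endogenous	hk060	none	none
ENDO_SYN_0061_at	endogenous	hk061	none	none
ENDO_SYN_0062_at	endogenous	hk062	none	none
ENDO_SYN_0063_at	endogenous	hk063	none	none
ENDO_SYN_0064_at	endogenous	hk064	none	none
ENDO_SYN_0065_at	endogenous	hk065	none	none
ENDO_SYN_0066_at	endogenous	hk066	none	none
ENDO_SYN_0067_at	endogenous	hk067	none	none
ENDO_SYN_0068_at	endogenous	hk068	none	none
ENDO_SYN_0069_at	endogenous	hk069	none	none
ENDO_SYN_0070_at	endogenous	hk070	none	none
ENDO_SYN_0071_at	endogenous	hk071	none	none
ENDO_SYN_0072_at	endogenous	hk072	none	none
ENDO_SYN_0073_at	endogenous	hk073	none	none
ENDO_SYN_0074_at	endogenous	hk074	none	none
ENDO_SYN_0075_at	endogenous	hk075	none	none
ENDO_SYN_0076_at	endogenous	hk076	none	none
ENDO_SYN_0077_at	endogenous	hk077	none	none
ENDO_SYN_0078_at	endogenous	hk078	none	none
ENDO_SYN_0079_at	endogenous	hk079	none	none
ENDO_SYN_0080_at	endogenous	hk080	none	none
ENDO_SYN_0081_at	endogenous	hk081	none	none
ENDO_SYN_0082_at	endogenous	hk082	none	none
ENDO_SYN_0083_at	endogenous	hk083	none	none
ENDO_SYN_0084_at	endogenous	hk084	none	none
ENDO_SYN_0085_at	endogenous	hk085	none	none
ENDO_SYN_0086_at	endogenous	hk086	none	none
ENDO_SYN_0087_at	endogenous	hk087	none	none
ENDO_SYN_0088_at	endogenous	hk088	none	none
ENDO_SYN_0089_at	endogenous	hk089	none	none
ENDO_SYN_0090_at	endogenous	hk090	none	none
ENDO_SYN_0091_at	endogenous	hk091	none	none
ENDO_SYN_0092_at	endogenous	hk092	none	none
ENDO_SYN_0093_at	endogenous	hk093	none	none
ENDO_SYN_0094_at	endogenous	hk094	none	none
ENDO_SYN_0095_at	endogenous	hk095	none	none
ENDO_SYN_0096_at	endogenous	hk096	none	none
ENDO_SYN_0097_at	endogenous	hk097	none	none
ENDO_SYN_0098_at	endogenous	hk098	none	none
ENDO_SYN_0099_at	endogenous	hk099	none	none
ENDO_SYN_0100_at	endogenous	hk100	none	none
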