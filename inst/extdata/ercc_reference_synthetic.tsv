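ercc_id	concentration_amol_per_ul
ERCC-S001	0.02
ERCC-S002	0.02
ERCC-S003	0.02
ERCC-S004	0.02
ERCC-S005	0.03817
ERCC-S006	0.03817
ERCC-S007	0.03817
ERCC-S008	0.03817
ERCC-S009	0.07286
ERCC-S010	0.07286
ERCC-S011	0.07286
ERCC-S012	0.07286
ERCC-S013	0.1391
ERCC-S014	0.1391
ERCC-S015	0.1391
ERCC-S016	0.1391
ERCC-S017	0.2654
ERCC-S018	0.2654
ERCC-S019	0.2654
ERCC-S020	0.2654
ERCC-S021	0.5066
ERCC-S022	0.5066
ERCC-S023	0.5066
ERCC-S024	0.5066
ERCC-S025	0.967
ERCC-S026	0.967
ERCC-S027	0.967
ERCC-S028	0.967
ERCC-S029	1.846
ERCC-S030	1.846
ERCC-S031	1.846
ERCC-S032	1.846
ERCC-S033	3.523
ERCC-S034	3.523
ERCC-S035	3.523
ERCC-S036	3.523
ERCC-S037	6.724
ERCC-S038	6.724
ERCC-S039	6.724
ERCC-S040	6.724
ERCC-S041	12.83
ERCC-S042	12.83
ERCC-S043	12.83
ERCC-S044	12.83
ERCC-S045	24.49
ERCC-S046	24.49
ERCC-S047	24.49
ERCC-S048	24.49
ERCC-S049	46.75
ERCC-S050	46.75
ERCC-S051	46.75
ERCC-S052	46.75
ERCC-S053	89.24
ERCC-S054	89.24
ERCC-S055	89.24
ERCC-S056	89.24
ERCC-S057	170.3
ERCC-S058	170.3
ERCC-S059	170.3
ERCC-S060	170.3
ERCC-S061	325.1
ERCC-S062	325.1
ERCC-S063	325.1
ERCC-S064	325.1
ERCC-S065	620.5
ERCC-S066	620.5
ERCC-S067	620.5
ERCC-S068	620.5
ERCC-S069	1184
ERCC-S070	1184
ERCC-S071	1184
ERCC-S072	1184
ERCC-S073	2260
ERCC-S074	2260
ERCC-S075	2260
ERCC-S076	2260
ERCC-S077	4314
ERCC-S078	4314
ERCC-S079	4314
ERCC-S080	4314
ERCC-S081	8235
ERCC-S082	8235
ERCC-S083	8235
ERCC-S084	8235
ERCC-S085	15720
ERCC-S086	15720
ERCC-S087	15720
ERCC-S088	15720
ERCC-S089	30000
ERCC-S090	30000
ERCC-S091	30000
ERCC-S092	30000
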