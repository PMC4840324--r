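subject_id	group	cancer_type	histology	stage	age_at_randomisation	matched_case
S001	control	none	none	none	62.4	S032
S002	control	none	none	none	60.5	S033
S003	control	none	none	none	55.6	S034
S004	control	none	none	none	63.3	S035
S005	control	none	none	none	68.1	S036
S006	control	none	none	none	66.1	S037
S007	control	none	none	none	60.7	S038
S008	control	none	none	none	62.8	S039
S009	control	none	none	none	60.5	S040
S010	control	none	none	none	64.5	S041
S011	control	none	none	none	64.7	S042
S012	control	none	none	none	58.4	S043
S013	control	none	none	none	58.6	S044
S014	control	none	none	none	65.4	S045
S015	control	none	none	none	63.9	S046
S016	control	none	none	none	64.1	S047
S017	control	none	none	none	68.7	S048
S018	control	none	none	none	55.4	S049
S019	control	none	none	none	66.4	S050
S020	control	none	none	none	60.2	S051
S021	control	none	none	none	61.2	S052
S022	control	none	none	none	64.6	S053
S023	control	none	none	none	63.2	S054
S024	control	none	none	none	62.1	S055
S025	control	none	none	none	62.6	S056
S026	control	none	none	none	58.5	S057
S027	control	none	none	none	61.9	S058
S028	control	none	none	none	65.3	S059
S029	control	none	none	none	61	S060
S030	control	none	none	none	66.2	S061
S031	control	none	none	none	62.2	S062
S032	case	type1	borderline serous	I	58.9	NA
S033	case	type1	borderline serous	I	68	NA
S034	case	type1	borderline serous	I	52.5	NA
S035	case	type1	borderline serous	I	60.7	NA
S036	case	type1	borderline serous	I	63.2	NA
S037	case	type1	borderline serous	I	55.6	NA
S038	case	type1	borderline mucinous	I	68.5	NA
S039	case	type1	borderline mucinous	I	66.2	NA
S040	case	type1	borderline endometrioid	I	62.8	NA
S041	case	type1	borderline endometrioid	I	64.5	NA
S042	case	type1	low-grade endometrioid	I	58.8	NA
S043	case	type1	low-grade endometrioid	I	65.6	NA
S044	case	type1	low-grade endometrioid	I	61	NA
S045	case	type1	low-grade endometrioid	II	61.7	NA
S046	case	type1	low-grade endometrioid	III	64.4	NA
S047	case	type1	clear cell	III	66.4	NA
S048	case	type1	clear cell	III	60	NA
S049	case	type1	clear cell	III	55.7	NA
S050	case	type1	adenocarcinoma	I	65.3	NA
S051	case	type2	high-grade serous	I	65.5	NA
S052	case	type2	high-grade serous	I	51.5	NA
S053	case	type2	high-grade serous	I	60.2	NA
S054	case	type2	high-grade serous	I	60.4	NA
S055	case	type2	high-grade serous	I	58.9	NA
S056	case	type2	high-grade serous	II	65.9	NA
S057	case	type2	high-grade serous	II	63.7	NA
S058	case	type2	high-grade serous	II	62.3	NA
S059	case	type2	high-grade serous	II	61.4	NA
S060	case	type2	high-grade serous	II	61.6	NA
S061	case	type2	high-grade serous	II	59.3	NA
S062	case	type2	high-grade serous	III	65.3	NA
S063	case	type2	high-grade serous	III	61.6	NA
S064	case	type2	high-grade serous	III	62.2	NA
S065	case	type2	high-grade serous	III	57.1	NA
S066	case	type2	high-grade serous	III	56.2	NA
S067	case	type2	high-grade serous	III	62.3	NA
S068	case	type2	high-grade serous	III	62.9	NA
S069	case	type2	high-grade serous	III	55.4	NA
S070	case	type2	high-grade serous	III	55.7	NA
S071	case	type2	high-grade serous	III	61.6	NA
S072	case	type2	high-grade serous	III	61.9	NA
S073	case	type2	high-grade serous	III	67.1	NA
S074	case	type2	high-grade endometrioid	I	57.2	NA
S075	case	type2	high-grade endometrioid	II	57.5	NA
S076	case	type2	high-grade endometrioid	III	64.7	NA
S077	case	type2	carcinosarcoma	III	65.3	NA
S078	case	type2	adenocarcinoma	I	62.3	NA
S079	case	type2	adenocarcinoma	II	64.6	NA
S080	case	type2	adenocarcinoma	III	59.9	NA
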