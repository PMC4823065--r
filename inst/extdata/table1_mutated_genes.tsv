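# relapsekit fixture: study Table 1, candidate relapse-associated mutated genes (3 WES trio patients)
source_table	patient	category	gene
T1	ALL001	shared	OXTR
T1	ALL001	shared	TBX21
T1	ALL001	shared	STEAP3
T1	ALL001	shared	SLURP1
T1	ALL001	shared	CSPP1
T1	ALL001	shared	KDM6A
T1	ALL001	shared	PTPN21
T1	ALL002	diagnosis_specific	NRF1
T1	ALL002	diagnosis_specific	MARCKS
T1	ALL002	diagnosis_specific	USP11
T1	ALL002	diagnosis_specific	ELK1
T1	ALL002	diagnosis_specific	MYC
T1	ALL002	shared	CREBBP
T1	ALL002	shared	RGS11
T1	ALL002	relapse_specific	USP54
T1	ALL002	relapse_specific	NCOR2
T1	ALL003	diagnosis_specific	USP54
T1	ALL003	diagnosis_specific	GABRA3
T1	ALL003	diagnosis_specific	KRAS
T1	ALL003	diagnosis_specific	SETD2
T1	ALL003	relapse_specific	MYH7
T1	ALL003	relapse_specific	NYNRIN
T1	ALL003	relapse_specific	ODZ1
T1	ALL003	relapse_specific	ZIC3
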