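# relapsekit fixture: study Table 2, recurring gene mutations (discovery n=3 + extension n=28 relapsed; 30 non-relapsed)
source_table	patient	group	cohort	gene	mutation_id	aa_change	effect	status
T2	ALL002	relapsed	discovery	CREBBP	c.4337G>A	p.Arg1446His	nonsynonymous	shared
T2	ALL030	relapsed	extension	CREBBP	c.5098C>A	p.Q1700K	nonsynonymous	relapse_specific
T2	ALL056	relapsed	extension	CREBBP	c.3710G>A	p.C1237Y	nonsynonymous	shared
T2	ALL065	relapsed	extension	CREBBP	c.4463C>T	p.P1488L	nonsynonymous	shared
T2	ALL003	relapsed	discovery	KRAS	c.34G>C	p.G12R	nonsynonymous	diagnosis_specific
T2	ALL064	relapsed	extension	KRAS	c.173C>T	p.T58I	nonsynonymous	shared
T2	ALL024	relapsed	extension	KRAS	c.38G>A	p.G13D	nonsynonymous	shared
T2	ALL001	relapsed	discovery	PTPN21	c.1573C>G	p.Pro525Ala	nonsynonymous	shared
T2	ALL001	relapsed	discovery	PTPN21	c.1975G>A	p.Ala659Thr	nonsynonymous	shared
T2	ALL050	relapsed	extension	PTPN21	c.1514C>A	p.P505Q	nonsynonymous	relapse_specific
T2	ALL001	relapsed	discovery	KDM6A	c.2563_2564insG	p.Asn855ArgfsX20	frameshift	shared
T2	ALL062	relapsed	extension	KDM6A	c.4031_4051delinsGGG	p.Val1344_Arg1351delinsGlyGly	inframe_indel	shared
T2	ALL002	relapsed	discovery	USP54	c.3130A>T	p.Thr1044Ser	nonsynonymous	relapse_specific
T2	ALL003	relapsed	discovery	USP54	c.4250G>A	p.Arg1417His	nonsynonymous	diagnosis_specific
T2	ALL051	relapsed	extension	NR3C1	c.431_431delinsAG	p.D144EfsX11	frameshift	relapse_specific
T2	ALL061	relapsed	extension	NR3C1	c.640C>T	p.Q214X	stopgain	relapse_specific
T2	ALL002	relapsed	discovery	MYC	c.221C>G	p.Pro74Arg	nonsynonymous	diagnosis_specific
T2	ALL037	relapsed	extension	MYC	c.293G>A	p.R98Q	nonsynonymous	relapse_specific
T2	ALLN018	non_relapsed	extension	MYC	c.223C>T	p.P75S	nonsynonymous	diagnosis_only_nonrelapsed
T2	ALL001	relapsed	discovery	TBX21	c.875_876insGG	p.Phe292LeufsX12	frameshift	shared
T2	ALLN011	non_relapsed	extension	TBX21	c.76G>C	p.A26P	nonsynonymous	diagnosis_only_nonrelapsed
T2	ALL003	relapsed	discovery	SETD2	c.7517_7518insGGT	p.Lys2506_His2507insVal	inframe_indel	diagnosis_specific
T2	ALL024	relapsed	extension	SETD2	c.5345G>A	p.W1782X	stopgain	shared
T2	ALL024	relapsed	extension	SETD2	c.4808A>G	p.H1603R	nonsynonymous	shared
T2	ALL063	relapsed	extension	SETD2	c.4874G>A	p.R1625H	nonsynonymous	shared
T2	ALL063	relapsed	extension	SETD2	c.1508_1509insTTCG	p.Glu503AspfsX18	frameshift	shared
T2	ALL066	relapsed	extension	SETD2	c.7199_7201delinsCT	p.Asp2400AlafsX11	frameshift	relapse_specific
T2	ALLN019	non_relapsed	extension	PAX5	c.77T>G	p.V26G	nonsynonymous	diagnosis_only_nonrelapsed
T2	ALLN024	non_relapsed	extension	PAX5	c.191G>T	p.C64F	nonsynonymous	diagnosis_only_nonrelapsed
T2	ALL026	relapsed	extension	PAX5	c.239C>G	p.P80R	nonsynonymous	shared
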