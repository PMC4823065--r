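# relapsekit fixture: study Table 3, read counts for 25 confirmed somatic mutations (3 WES trio patients)
# printed_pct is the published '%Variant in tumor'; formula_discordant marks the two printed cells that disagree with the blast-adjustment formula
source_table	patient	gene	aa_change	stage	blast_pct	var_reads	wt_reads	printed_pct	formula_discordant
T3	ALL001	OXTR	p.Ser377Ile	diagnosis	90	23	18	62.3	FALSE
T3	ALL001	OXTR	p.Ser377Ile	relapse	92	32	33	53.5	FALSE
T3	ALL001	OXTR	p.Ser377Ile	CR		0	83	0	FALSE
T3	ALL001	TBX21	p.Phe292LeufsX12	diagnosis	90	25	41	42.1	FALSE
T3	ALL001	TBX21	p.Phe292LeufsX12	relapse	92	46	57	48.5	FALSE
T3	ALL001	TBX21	p.Phe292LeufsX12	CR		0	114	0	FALSE
T3	ALL001	STEAP3	p.Pro210Leu	diagnosis	90	5	10	37	FALSE
T3	ALL001	STEAP3	p.Pro210Leu	relapse	92	17	15	57.7	FALSE
T3	ALL001	STEAP3	p.Pro210Leu	CR		0	73	0	FALSE
T3	ALL001	SLURP1	p.Cys25Phe	diagnosis	90	10	25	31.7	FALSE
T3	ALL001	SLURP1	p.Cys25Phe	relapse	92	22	36	41.2	FALSE
T3	ALL001	SLURP1	p.Cys25Phe	CR		0	118	0	FALSE
T3	ALL001	CSPP1	p.Leu1103Pro	diagnosis	90	30	41	46.9	FALSE
T3	ALL001	CSPP1	p.Leu1103Pro	relapse	92	21	26	48.6	FALSE
T3	ALL001	CSPP1	p.Leu1103Pro	CR		0	97	0	FALSE
T3	ALL001	KDM6A	p.Asn855ArgfsX20	diagnosis	90	35	81	33.5	FALSE
T3	ALL001	KDM6A	p.Asn855ArgfsX20	relapse	92	44	66	43.5	FALSE
T3	ALL001	KDM6A	p.Asn855ArgfsX20	CR		0	70	0	FALSE
T3	ALL001	PTPN21	p.Pro525Ala	diagnosis	90	10	13	48.3	FALSE
T3	ALL001	PTPN21	p.Pro525Ala	relapse	92	21	20	55.7	FALSE
T3	ALL001	PTPN21	p.Pro525Ala	CR		0	107	0	FALSE
T3	ALL001	PTPN21	p.Ala659Thr	diagnosis	90	12	13	53.3	FALSE
T3	ALL001	PTPN21	p.Ala659Thr	relapse	92	20	21	53	FALSE
T3	ALL001	PTPN21	p.Ala659Thr	CR		0	29	0	FALSE
T3	ALL002	CREBBP	p.Arg1446His	diagnosis	95	37	50	44.8	FALSE
T3	ALL002	CREBBP	p.Arg1446His	relapse	33	21	107	49.7	FALSE
T3	ALL002	CREBBP	p.Arg1446His	CR		0	81	0	FALSE
T3	ALL002	RGS11	p.Arg409Arg	diagnosis	95	14	23	39.8	FALSE
T3	ALL002	RGS11	p.Arg409Arg	relapse	33	21	120	45.1	FALSE
T3	ALL002	RGS11	p.Arg409Arg	CR		0	23	0	FALSE
T3	ALL002	USP54	p.Arg1417His	diagnosis	95	0	50	0	FALSE
T3	ALL002	USP54	p.Arg1417His	relapse	33	13	62	52.5	FALSE
T3	ALL002	USP54	p.Arg1417His	CR		0	55	0	FALSE
T3	ALL002	NCOR2	p.Ala2013Thr	diagnosis	95	0	37	0	FALSE
T3	ALL002	NCOR2	p.Ala2013Thr	relapse	33	7	26	64.8	TRUE
T3	ALL002	NCOR2	p.Ala2013Thr	CR		0	22	0	FALSE
T3	ALL002	NRF1	p.Lys226Ile	diagnosis	95	44	33	60.9	TRUE
T3	ALL002	NRF1	p.Lys226Ile	relapse	33	1	72	4.2	FALSE
T3	ALL002	NRF1	p.Lys226Ile	CR		0	42	0	FALSE
T3	ALL002	MARCKS	p.Ala15Thr	diagnosis	95	11	13	48.2	FALSE
T3	ALL002	MARCKS	p.Ala15Thr	relapse	33	0	49	0	FALSE
T3	ALL002	MARCKS	p.Ala15Thr	CR		0	23	0	FALSE
T3	ALL002	USP11	p.Ala739Thr	diagnosis	95	31	24	59.3	FALSE
T3	ALL002	USP11	p.Ala739Thr	relapse	33	0	44	0	FALSE
T3	ALL002	USP11	p.Ala739Thr	CR		0	40	0	FALSE
T3	ALL002	ELK1	p.Pro238Leu	diagnosis	95	21	31	42.5	FALSE
T3	ALL002	ELK1	p.Pro238Leu	relapse	33	0	47	0	FALSE
T3	ALL002	ELK1	p.Pro238Leu	CR		0	42	0	FALSE
T3	ALL002	MYC	p.Pro74Arg	diagnosis	95	10	5	70.2	FALSE
T3	ALL002	MYC	p.Pro74Arg	relapse	33	0	37	0	FALSE
T3	ALL002	MYC	p.Pro74Arg	CR		0	31	0	FALSE
T3	ALL003	USP54	p.Thr1044Ser	diagnosis	93	37	115	26.2	FALSE
T3	ALL003	USP54	p.Thr1044Ser	relapse	74	0	118	0	FALSE
T3	ALL003	USP54	p.Thr1044Ser	CR		6	166	3.5	FALSE
T3	ALL003	GABRA3	p.Ser60Gly	diagnosis	93	25	39	42	FALSE
T3	ALL003	GABRA3	p.Ser60Gly	relapse	74	0	39	0	FALSE
T3	ALL003	GABRA3	p.Ser60Gly	CR		0	70	0	FALSE
T3	ALL003	KRAS	p.Gly12Arg	diagnosis	93	39	85	33.8	FALSE
T3	ALL003	KRAS	p.Gly12Arg	relapse	74	0	138	0	FALSE
T3	ALL003	KRAS	p.Gly12Arg	CR		0	107	0	FALSE
T3	ALL003	SETD2	p.Lys2506_His2507insVal	diagnosis	93	61	57	55.6	FALSE
T3	ALL003	SETD2	p.Lys2506_His2507insVal	relapse	74	0	83	0	FALSE
T3	ALL003	SETD2	p.Lys2506_His2507insVal	CR		6	107	5.3	FALSE
T3	ALL003	MYH7	p.Leu1104Gln	diagnosis	93	0	73	0	FALSE
T3	ALL003	MYH7	p.Leu1104Gln	relapse	74	26	38	54.9	FALSE
T3	ALL003	MYH7	p.Leu1104Gln	CR		0	65	0	FALSE
T3	ALL003	NYNRIN	p.Thr652SerfsX50	diagnosis	93	0	24	0	FALSE
T3	ALL003	NYNRIN	p.Thr652SerfsX50	relapse	74	33	44	57.9	FALSE
T3	ALL003	NYNRIN	p.Thr652SerfsX50	CR		0	37	0	FALSE
T3	ALL003	ODZ1		diagnosis	93	0	54	0	FALSE
T3	ALL003	ODZ1		relapse	74	19	37	45.8	FALSE
T3	ALL003	ODZ1		CR		0	60	0	FALSE
T3	ALL003	ZIC3	p.Arg123His	diagnosis	93	0	39	0	FALSE
T3	ALL003	ZIC3	p.Arg123His	relapse	74	10	14	56.3	FALSE
T3	ALL003	ZIC3	p.Arg123His	CR		0	34	0	FALSE
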