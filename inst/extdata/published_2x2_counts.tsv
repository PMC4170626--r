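panel	grouping	gene	group1	group2	meth1	n1	meth2	n2	printed_p
2A	recurrence	CCND2	non-recurrent	recurrent	2	17	10	19	0.014
2A	recurrence	CCNA1	non-recurrent	recurrent	4	17	11	19	0.048
2A	recurrence	CALCA	non-recurrent	recurrent	4	17	10	19	0.097
2A	recurrence	AIM1	non-recurrent	recurrent	8	17	14	19	0.171
2A	recurrence	NID2	non-recurrent	recurrent	3	17	13	19	0.003
2A	recurrence	ARF	non-recurrent	recurrent	2	17	0	19	0.216
2A	recurrence	TIMP3	non-recurrent	recurrent	10	17	4	19	0.039
2A	recurrence	RARB2	non-recurrent	recurrent	5	17	3	19	0.434
2B-I	case-control	CCND2	control	case	0	56	38	148	<0.0001
2B-I	case-control	CCNA1	control	case	10	60	50	73	<0.0001
2B-I	case-control	CALCA	control	case	16	56	94	148	<0.0001
2B-II	grade	CCND2	LGUCC	HGUCC	35	101	3	24	0.047
2B-II	grade	CCNA1	LGUCC	HGUCC	35	52	7	14	0.348
2B-II	grade	CALCA	LGUCC	HGUCC	76	101	8	24	0.0002
2B-II	stage	CCND2	non-invasive	invasive	3	32	35	92	0.002
2B-II	stage	CCNA1	non-invasive	invasive	9	16	34	49	0.372
2B-II	stage	CALCA	non-invasive	invasive	17	32	67	92	0.049
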