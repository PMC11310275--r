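chr1	0	2300000	p36.33	gneg
chr1	2300000	5400000	p36.32	gpos25
chr1	5400000	7200000	p36.31	gneg
chr1	7200000	9200000	p36.23	gpos25
chr1	9200000	12700000	p36.22	gneg
chr1	12700000	16200000	p36.21	gpos50
chr1	16200000	20400000	p36.13	gneg
chr1	20400000	23900000	p36.12	gpos25
chr1	23900000	28000000	p36.11	gneg
chr1	28000000	30200000	p35.3	gpos25
chr1	30200000	32400000	p35.2	gneg
chr1	32400000	34600000	p35.1	gpos25
chr1	34600000	40100000	p34.3	gneg
chr1	40100000	44100000	p34.2	gpos25
chr1	44100000	46800000	p34.1	gneg
chr1	46800000	50700000	p33	gpos75
chr1	50700000	56100000	p32.3	gneg
chr1	56100000	59000000	p32.2	gpos50
chr1	59000000	61300000	p32.1	gneg
chr1	61300000	68900000	p31.3	gpos50
chr1	68900000	69700000	p31.2	gneg
chr1	69700000	84900000	p31.1	gpos100
chr1	84900000	88400000	p22.3	gneg
chr1	88400000	92000000	p22.2	gpos75
chr1	92000000	94700000	p22.1	gneg
chr1	94700000	99700000	p21.3	gpos75
chr1	99700000	102200000	p21.2	gneg
chr1	102200000	107200000	p21.1	gpos100
chr1	107200000	111800000	p13.3	gneg
chr1	111800000	116100000	p13.2	gpos50
chr1	116100000	117800000	p13.1	gneg
chr1	117800000	120600000	p12	gpos50
chr1	120600000	121500000	p11.2	gneg
chr1	121500000	125000000	p11.1	acen
chr1	125000000	128900000	q11	acen
chr1	128900000	142600000	q12	gvar
chr1	142600000	147000000	q21.1	gneg
chr1	147000000	150300000	q21.2	gpos50
chr1	150300000	155000000	q21.3	gneg
chr1	155000000	156500000	q22	gpos50
chr1	156500000	165500000	q23	gneg
chr1	165500000	173000000	q24	gpos50
chr1	173000000	185800000	q25	gneg
chr1	185800000	198700000	q31	gpos100
chr1	198700000	207200000	q32.1	gneg
chr1	207200000	211500000	q32.2	gpos25
chr1	211500000	214500000	q32.3	gneg
chr1	214500000	224100000	q41	gpos50
chr1	224100000	236600000	q42	gneg
chr1	236600000	243700000	q43	gpos75
chr1	243700000	249250621	q44	gneg
chr22	0	3800000	p13	gvar
chr22	3800000	8300000	p12	stalk
chr22	8300000	12200000	p11.2	gvar
chr22	12200000	14700000	p11.1	acen
chr22	14700000	17900000	q11.1	acen
chr22	17900000	22200000	q11.2	gneg
chr22	22200000	23500000	q12.1	gpos25
chr22	23500000	25900000	q12.2	gneg
chr22	25900000	29600000	q12.3	gpos25
chr22	29600000	32200000	q13.1	gneg
chr22	32200000	37600000	q13.2	gpos50
chr22	37600000	41000000	q13.31	gneg
chr22	41000000	44200000	q13.32	gpos50
chr22	44200000	51304566	q13.33	gneg
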