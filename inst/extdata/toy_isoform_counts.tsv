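gene_id	isoform_id	sample1	sample2	sample3	sample4	sample5	sample6	sample7	sample8	sample9	sample10	sample11	sample12
gene01	gene01.iso1	10	5	12	11	0	3	19	13	12	21	2	29
gene01	gene01.iso2	19	1	8	12	11	12	0	9	8	6	7	14
gene02	gene02.iso1	35	36	21	36	4	19	3	39	20	32	25	11
gene02	gene02.iso2	7	30	30	44	12	47	5	3	9	5	3	15
gene02	gene02.iso3	3	3	15	6	31	8	13	2	26	7	11	5
gene03	gene03.iso1	2	5	2	5	5	5	2	6	19	4	0	4
gene04	gene04.iso1	2	2	0	13	8	8	18	2	9	7	13	6
gene04	gene04.iso2	41	30	25	47	56	25	8	13	8	5	13	12
gene04	gene04.iso3	4	2	5	1	4	0	12	3	2	6	6	7
gene04	gene04.iso4	3	11	2	10	5	18	5	4	5	7	5	8
gene05	gene05.iso1	8	10	3	4	5	14	11	13	16	3	12	16
gene05	gene05.iso2	3	12	0	3	5	2	25	1	22	17	21	12
gene06	gene06.iso1	17	11	14	47	29	3	23	20	2	34	26	9
gene06	gene06.iso2	2	10	16	16	5	0	7	5	12	14	4	9
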