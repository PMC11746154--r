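part	complex_chain	complex_resno	template_resno	elety
N	S	1	1	CA
N	S	2	2	CA
N	S	3	3	CA
N	S	4	4	CA
N	S	5	5	CA
N	S	6	6	CA
N	S	7	7	CA
N	S	8	8	CA
N	S	9	9	CA
N	S	10	10	CA
N	S	11	11	CA
N	S	12	12	CA
N	S	13	13	CA
N	S	14	14	CA
N	S	15	15	CA
N	S	16	16	CA
N	S	17	17	CA
N	S	18	18	CA
N	S	19	19	CA
N	S	20	20	CA
C	S	21	21	CA
C	S	22	22	CA
C	S	23	23	CA
C	S	24	24	CA
C	S	25	25	CA
C	S	26	26	CA
C	S	27	27	CA
C	S	28	28	CA
C	S	29	29	CA
C	S	30	30	CA
C	S	31	31	CA
C	S	32	32	CA
C	S	33	33	CA
C	S	34	34	CA
C	S	35	35	CA
C	S	36	36	CA
C	S	37	37	CA
C	S	38	38	CA
C	S	39	39	CA
C	S	40	40	CA
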