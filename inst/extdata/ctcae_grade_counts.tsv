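grade	neutropenia	leukocytopenia	thrombocytopenia	maximal
0	44	39	27	23
1	0	7	12	11
2	6	22	14	8
3	18	24	23	15
4	28	4	20	39
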