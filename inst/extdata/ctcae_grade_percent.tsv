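grade	neutropenia	leukocytopenia	thrombocytopenia	maximal
0	45.8	40.6	28.1	24.0
1	0.0	7.3	12.5	11.5
2	6.3	22.9	14.6	8.3
3	18.8	25.0	24.0	15.6
4	29.2	4.2	20.8	40.6
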