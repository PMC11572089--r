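sample_size	n_iv	(2)	(7)	(30)	(10,10)	(50,50)
50	3	0.002	0	0	0.001	0.003
50	5	0.005	0.002	0.003	0.009	0.007
50	10	0.013	0.004	0.011	0.015	0.015
100	3	0	0	0	0	0
100	5	0	0	0	0	0
100	10	0	0.001	0.001	0	0.001
200	3	0.002	0	0	0	0
200	5	0	0	0	0	0
200	10	0	0	0	0	0
500	3	0	0	0	0	0
500	5	0	0	0	0	0
500	10	0	0	0	0	0
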