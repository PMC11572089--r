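sample_size	n_iv	shape	AUC>=0.6	AUC>=0.65	AUC>=0.7	BA>=0.6	BA>=0.65	BA>=0.7
50	3	(2)	0.136	0.08	0.04	0.164	0.084	0.048
50	5	(2)	0.126	0.075	0.031	0.173	0.077	0.04
50	10	(2)	0.133	0.085	0.027	0.178	0.086	0.039
100	3	(2)	0.092	0.042	0.02	0.112	0.053	0.032
100	5	(2)	0.107	0.052	0.027	0.12	0.055	0.032
100	10	(2)	0.085	0.037	0.016	0.101	0.039	0.019
200	3	(2)	0.045	0.025	0.019	0.058	0.038	0.032
200	5	(2)	0.076	0.044	0.029	0.079	0.046	0.031
200	10	(2)	0.106	0.062	0.036	0.11	0.066	0.04
500	3	(2)	0	0	0	0	0	0
500	5	(2)	0	0	0	0	0	0
500	10	(2)	0	0	0	0	0	0
50	3	(7)	0.109	0.088	0.049	0.2	0.16	0.124
50	5	(7)	0.135	0.1	0.055	0.174	0.122	0.08
50	10	(7)	0.147	0.105	0.036	0.188	0.117	0.054
100	3	(7)	0.041	0.027	0.017	0.116	0.102	0.092
100	5	(7)	0.077	0.058	0.037	0.135	0.111	0.091
100	10	(7)	0.123	0.08	0.046	0.139	0.089	0.056
200	3	(7)	0	0	0	0.028	0.028	0.028
200	5	(7)	0.004	0.004	0.002	0.016	0.016	0.014
200	10	(7)	0.023	0.02	0.015	0.035	0.032	0.027
500	3	(7)	0	0	0	0	0	0
500	5	(7)	0	0	0	0	0	0
500	10	(7)	0.003	0.003	0.003	0.003	0.003	0.003
50	3	(30)	0.033	0.029	0.018	0.277	0.271	0.26
50	5	(30)	0.066	0.054	0.035	0.279	0.26	0.241
50	10	(30)	0.125	0.101	0.061	0.225	0.185	0.148
100	3	(30)	0.005	0.003	0.002	0.126	0.124	0.123
100	5	(30)	0.01	0.008	0.006	0.107	0.105	0.103
100	10	(30)	0.044	0.031	0.022	0.112	0.097	0.088
200	3	(30)	0	0	0	0.028	0.028	0.028
200	5	(30)	0.003	0.003	0.003	0.015	0.015	0.015
200	10	(30)	0.02	0.02	0.018	0.032	0.032	0.03
500	3	(30)	0	0	0	0	0	0
500	5	(30)	0	0	0	0	0	0
500	10	(30)	0.003	0.003	0.003	0.003	0.003	0.003
50	3	(10,10)	0.039	0.031	0.015	0.759	0.736	0.722
50	5	(10,10)	0.071	0.059	0.035	0.579	0.558	0.535
50	10	(10,10)	0.112	0.089	0.055	0.356	0.314	0.28
100	3	(10,10)	0.006	0.006	0.004	0.953	0.951	0.948
100	5	(10,10)	0.019	0.012	0.011	0.866	0.859	0.857
100	10	(10,10)	0.074	0.063	0.046	0.578	0.565	0.549
200	3	(10,10)	0.001	0.001	0	0.028	0.028	0.027
200	5	(10,10)	0.004	0.004	0.004	0.015	0.015	0.015
200	10	(10,10)	0.028	0.024	0.019	0.039	0.035	0.03
500	3	(10,10)	0	0	0	0	0	0
500	5	(10,10)	0	0	0	0	0	0
500	10	(10,10)	0.009	0.009	0.008	0.009	0.009	0.008
50	3	(50,50)	0.028	0.025	0.015	0.768	0.755	0.746
50	5	(50,50)	0.053	0.04	0.025	0.653	0.629	0.614
50	10	(50,50)	0.096	0.074	0.043	0.405	0.366	0.339
100	3	(50,50)	0.008	0.006	0.004	0.963	0.959	0.956
100	5	(50,50)	0.02	0.017	0.012	0.871	0.867	0.861
100	10	(50,50)	0.06	0.046	0.034	0.566	0.55	0.538
200	3	(50,50)	0	0	0	0.028	0.028	0.028
200	5	(50,50)	0.002	0.002	0.002	0.014	0.014	0.014
200	10	(50,50)	0.03	0.03	0.026	0.043	0.043	0.039
500	3	(50,50)	0	0	0	0	0	0
500	5	(50,50)	0	0	0	0	0	0
500	10	(50,50)	0.003	0.003	0.003	0.003	0.003	0.003
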