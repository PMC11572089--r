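sample_size	n_iv	shape	AUC>=0.6	AUC>=0.65	AUC>=0.7	BA>=0.6	BA>=0.65	BA>=0.7
50	3	(2)	0.147	0.093	0.042	0.205	0.109	0.061
50	5	(2)	0.123	0.08	0.032	0.164	0.085	0.052
50	10	(2)	0.136	0.079	0.024	0.174	0.081	0.032
100	3	(2)	0.099	0.049	0.028	0.124	0.062	0.041
100	5	(2)	0.095	0.048	0.023	0.107	0.05	0.027
100	10	(2)	0.077	0.03	0.015	0.087	0.034	0.018
200	3	(2)	0.065	0.032	0.018	0.074	0.041	0.027
200	5	(2)	0.077	0.054	0.03	0.08	0.056	0.032
200	10	(2)	0.114	0.066	0.031	0.116	0.067	0.032
500	3	(2)	0.001	0.001	0.001	0.001	0.001	0.001
500	5	(2)	0.001	0.001	0.001	0.001	0.001	0.001
500	10	(2)	0	0	0	0	0	0
50	3	(7)	0.112	0.085	0.045	0.199	0.16	0.124
50	5	(7)	0.134	0.092	0.051	0.172	0.116	0.077
50	10	(7)	0.136	0.095	0.04	0.171	0.104	0.052
100	3	(7)	0.041	0.034	0.022	0.113	0.104	0.092
100	5	(7)	0.078	0.054	0.044	0.127	0.102	0.092
100	10	(7)	0.108	0.072	0.036	0.121	0.084	0.05
200	3	(7)	0.003	0.003	0.003	0.021	0.021	0.021
200	5	(7)	0.007	0.006	0.004	0.018	0.017	0.015
200	10	(7)	0.029	0.025	0.021	0.038	0.034	0.03
500	3	(7)	0	0	0	0	0	0
500	5	(7)	0	0	0	0	0	0
500	10	(7)	0.002	0.001	0.001	0.002	0.001	0.001
50	3	(30)	0.028	0.023	0.015	0.283	0.275	0.268
50	5	(30)	0.065	0.052	0.032	0.256	0.241	0.221
50	10	(30)	0.102	0.079	0.046	0.193	0.162	0.133
100	3	(30)	0.003	0.003	0.003	0.104	0.104	0.104
100	5	(30)	0.015	0.014	0.013	0.111	0.109	0.108
100	10	(30)	0.047	0.033	0.025	0.119	0.103	0.095
200	3	(30)	0.002	0.002	0.001	0.02	0.02	0.019
200	5	(30)	0.002	0.002	0.002	0.014	0.014	0.014
200	10	(30)	0.021	0.016	0.014	0.031	0.026	0.024
500	3	(30)	0.001	0.001	0.001	0.001	0.001	0.001
500	5	(30)	0	0	0	0	0	0
500	10	(30)	0	0	0	0	0	0
50	3	(10,10)	0.043	0.039	0.021	0.302	0.295	0.277
50	5	(10,10)	0.067	0.057	0.038	0.237	0.223	0.205
50	10	(10,10)	0.103	0.084	0.04	0.188	0.161	0.119
100	3	(10,10)	0.009	0.008	0.007	0.105	0.103	0.102
100	5	(10,10)	0.017	0.014	0.011	0.103	0.101	0.097
100	10	(10,10)	0.056	0.043	0.031	0.123	0.107	0.095
200	3	(10,10)	0.004	0.004	0.003	0.022	0.022	0.021
200	5	(10,10)	0.003	0.003	0.002	0.014	0.014	0.013
200	10	(10,10)	0.031	0.027	0.024	0.039	0.034	0.031
500	3	(10,10)	0.001	0.001	0.001	0.001	0.001	0.001
500	5	(10,10)	0	0	0	0	0	0
500	10	(10,10)	0.01	0.01	0.009	0.01	0.01	0.009
50	3	(50,50)	0.035	0.024	0.012	0.312	0.299	0.288
50	5	(50,50)	0.05	0.041	0.028	0.257	0.239	0.228
50	10	(50,50)	0.101	0.081	0.05	0.233	0.202	0.173
100	3	(50,50)	0.007	0.005	0.005	0.106	0.104	0.104
100	5	(50,50)	0.025	0.02	0.017	0.12	0.115	0.112
100	10	(50,50)	0.053	0.038	0.028	0.114	0.098	0.088
200	3	(50,50)	0.002	0.002	0.001	0.02	0.02	0.019
200	5	(50,50)	0.005	0.005	0.003	0.016	0.016	0.014
200	10	(50,50)	0.027	0.026	0.023	0.037	0.036	0.033
500	3	(50,50)	0	0	0	0	0	0
500	5	(50,50)	0	0	0	0	0	0
500	10	(50,50)	0.003	0.002	0.002	0.003	0.002	0.002
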