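sample_size	n_iv	shape	AUC>=0.6	AUC>=0.65	AUC>=0.7	BA>=0.6	BA>=0.65	BA>=0.7
50	3	(2)	0.284	0.215	0.165	0.319	0.215	0.169
50	5	(2)	0.296	0.211	0.158	0.322	0.211	0.162
50	10	(2)	0.276	0.2	0.15	0.306	0.2	0.156
100	3	(2)	0.178	0.095	0.046	0.195	0.096	0.05
100	5	(2)	0.199	0.105	0.055	0.216	0.108	0.059
100	10	(2)	0.177	0.098	0.043	0.198	0.1	0.045
200	3	(2)	0.109	0.034	0.011	0.113	0.034	0.011
200	5	(2)	0.107	0.029	0.01	0.115	0.03	0.01
200	10	(2)	0.115	0.032	0.009	0.12	0.033	0.009
500	3	(2)	0.033	0.006	0.005	0.036	0.006	0.005
500	5	(2)	0.034	0.008	0.003	0.035	0.008	0.003
500	10	(2)	0.027	0.001	0	0.027	0.001	0
50	3	(7)	0.255	0.176	0.128	0.277	0.176	0.13
50	5	(7)	0.274	0.192	0.139	0.3	0.192	0.143
50	10	(7)	0.293	0.216	0.156	0.316	0.216	0.161
100	3	(7)	0.22	0.137	0.07	0.23	0.138	0.072
100	5	(7)	0.192	0.105	0.051	0.211	0.107	0.052
100	10	(7)	0.203	0.115	0.059	0.23	0.118	0.065
200	3	(7)	0.131	0.049	0.017	0.134	0.05	0.017
200	5	(7)	0.111	0.038	0.013	0.114	0.039	0.013
200	10	(7)	0.119	0.037	0.01	0.128	0.04	0.01
500	3	(7)	0.028	0.007	0.003	0.028	0.007	0.003
500	5	(7)	0.029	0.004	0	0.03	0.004	0
500	10	(7)	0.025	0	0	0.025	0	0
50	3	(30)	0.258	0.181	0.135	0.282	0.181	0.139
50	5	(30)	0.293	0.204	0.15	0.315	0.204	0.154
50	10	(30)	0.287	0.195	0.152	0.319	0.195	0.156
100	3	(30)	0.2	0.12	0.063	0.216	0.124	0.066
100	5	(30)	0.212	0.116	0.07	0.226	0.117	0.073
100	10	(30)	0.19	0.099	0.038	0.215	0.101	0.038
200	3	(30)	0.124	0.051	0.027	0.132	0.053	0.027
200	5	(30)	0.107	0.024	0.004	0.109	0.024	0.005
200	10	(30)	0.109	0.035	0.009	0.118	0.035	0.009
500	3	(30)	0.04	0.011	0.005	0.041	0.011	0.005
500	5	(30)	0.04	0.006	0.002	0.041	0.006	0.002
500	10	(30)	0.023	0	0	0.023	0	0
50	3	(10,10)	0.272	0.198	0.142	0.298	0.198	0.147
50	5	(10,10)	0.282	0.202	0.145	0.31	0.202	0.151
50	10	(10,10)	0.274	0.201	0.142	0.297	0.201	0.149
100	3	(10,10)	0.191	0.109	0.042	0.209	0.114	0.045
100	5	(10,10)	0.193	0.126	0.057	0.207	0.128	0.061
100	10	(10,10)	0.18	0.102	0.049	0.205	0.105	0.053
200	3	(10,10)	0.124	0.041	0.017	0.127	0.041	0.017
200	5	(10,10)	0.128	0.042	0.01	0.13	0.042	0.011
200	10	(10,10)	0.12	0.041	0.011	0.129	0.042	0.013
500	3	(10,10)	0.046	0.009	0.003	0.046	0.009	0.003
500	5	(10,10)	0.034	0.003	0.001	0.036	0.003	0.001
500	10	(10,10)	0.025	0.001	0	0.026	0.001	0
50	3	(50,50)	0.277	0.207	0.153	0.306	0.207	0.157
50	5	(50,50)	0.298	0.215	0.153	0.327	0.215	0.156
50	10	(50,50)	0.259	0.178	0.138	0.284	0.178	0.14
100	3	(50,50)	0.199	0.122	0.065	0.215	0.124	0.068
100	5	(50,50)	0.21	0.119	0.054	0.225	0.119	0.054
100	10	(50,50)	0.185	0.096	0.047	0.21	0.097	0.053
200	3	(50,50)	0.114	0.028	0.009	0.12	0.028	0.009
200	5	(50,50)	0.105	0.025	0.008	0.114	0.025	0.008
200	10	(50,50)	0.107	0.042	0.016	0.115	0.043	0.016
500	3	(50,50)	0.039	0.012	0.006	0.041	0.012	0.006
500	5	(50,50)	0.029	0.006	0.001	0.03	0.006	0.001
500	10	(50,50)	0.022	0.001	0	0.023	0.001	0
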