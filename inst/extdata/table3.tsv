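sample_size	n_iv	shape	AUC>=0.6	AUC>=0.65	AUC>=0.7	BA>=0.6	BA>=0.65	BA>=0.7
50	3	(2)	0.284	0.206	0.158	0.319	0.206	0.162
50	5	(2)	0.267	0.178	0.121	0.297	0.178	0.131
50	10	(2)	0.296	0.218	0.153	0.331	0.218	0.162
100	3	(2)	0.191	0.119	0.058	0.216	0.119	0.063
100	5	(2)	0.197	0.111	0.05	0.213	0.113	0.056
100	10	(2)	0.204	0.104	0.048	0.226	0.105	0.053
200	3	(2)	0.12	0.046	0.012	0.125	0.048	0.013
200	5	(2)	0.109	0.04	0.015	0.112	0.041	0.016
200	10	(2)	0.093	0.031	0.005	0.099	0.031	0.007
500	3	(2)	0.036	0.007	0.003	0.037	0.007	0.003
500	5	(2)	0.035	0.006	0.001	0.035	0.006	0.001
500	10	(2)	0.035	0.001	0	0.035	0.001	0
50	3	(7)	0.28	0.217	0.168	0.303	0.217	0.171
50	5	(7)	0.268	0.182	0.131	0.304	0.182	0.137
50	10	(7)	0.269	0.193	0.136	0.3	0.193	0.139
100	3	(7)	0.196	0.108	0.058	0.219	0.11	0.06
100	5	(7)	0.179	0.103	0.038	0.193	0.104	0.041
100	10	(7)	0.194	0.097	0.046	0.207	0.099	0.048
200	3	(7)	0.128	0.048	0.015	0.133	0.048	0.016
200	5	(7)	0.113	0.038	0.015	0.12	0.038	0.015
200	10	(7)	0.109	0.035	0.011	0.114	0.035	0.011
500	3	(7)	0.035	0.008	0.004	0.036	0.008	0.004
500	5	(7)	0.032	0.004	0.001	0.033	0.004	0.001
500	10	(7)	0.021	0.001	0.001	0.021	0.001	0.001
50	3	(30)	0.286	0.212	0.158	0.304	0.212	0.161
50	5	(30)	0.287	0.204	0.158	0.307	0.204	0.161
50	10	(30)	0.261	0.183	0.139	0.291	0.183	0.142
100	3	(30)	0.202	0.125	0.069	0.22	0.126	0.072
100	5	(30)	0.198	0.113	0.056	0.218	0.115	0.058
100	10	(30)	0.193	0.1	0.048	0.214	0.103	0.048
200	3	(30)	0.13	0.049	0.022	0.138	0.049	0.022
200	5	(30)	0.119	0.04	0.009	0.127	0.041	0.009
200	10	(30)	0.138	0.031	0.008	0.142	0.032	0.008
500	3	(30)	0.039	0.008	0.005	0.039	0.008	0.005
500	5	(30)	0.025	0.005	0	0.025	0.005	0
500	10	(30)	0.026	0.005	0	0.026	0.005	0
50	3	(10,10)	0.282	0.21	0.153	0.323	0.217	0.165
50	5	(10,10)	0.285	0.206	0.148	0.317	0.206	0.153
50	10	(10,10)	0.279	0.191	0.136	0.312	0.194	0.142
100	3	(10,10)	0.206	0.129	0.076	0.23	0.135	0.08
100	5	(10,10)	0.208	0.123	0.058	0.224	0.125	0.061
100	10	(10,10)	0.204	0.117	0.051	0.22	0.12	0.052
200	3	(10,10)	0.112	0.04	0.021	0.118	0.041	0.021
200	5	(10,10)	0.106	0.036	0.008	0.115	0.036	0.009
200	10	(10,10)	0.113	0.041	0.008	0.119	0.041	0.009
500	3	(10,10)	0.037	0.006	0.003	0.037	0.006	0.003
500	5	(10,10)	0.023	0.002	0	0.023	0.002	0
500	10	(10,10)	0.024	0.002	0	0.025	0.002	0
50	3	(50,50)	0.261	0.194	0.135	0.301	0.202	0.144
50	5	(50,50)	0.271	0.19	0.151	0.307	0.19	0.156
50	10	(50,50)	0.28	0.19	0.136	0.323	0.192	0.144
100	3	(50,50)	0.2	0.13	0.068	0.223	0.138	0.075
100	5	(50,50)	0.215	0.116	0.052	0.229	0.117	0.059
100	10	(50,50)	0.183	0.097	0.03	0.206	0.1	0.033
200	3	(50,50)	0.128	0.043	0.014	0.133	0.044	0.014
200	5	(50,50)	0.1	0.028	0.009	0.103	0.029	0.009
200	10	(50,50)	0.115	0.034	0.005	0.119	0.034	0.005
500	3	(50,50)	0.044	0.014	0.009	0.049	0.014	0.009
500	5	(50,50)	0.027	0.003	0	0.028	0.003	0
500	10	(50,50)	0.033	0.002	0	0.034	0.002	0
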