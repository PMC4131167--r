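gene	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10	s11	s12
g001	-1.045	0.343	0.909	-0.253	0.792	0.451	1.067	-0.596	-0.34	1.326	0.142	-0.86
g002	-0.109	-2.069	-0.775	1.036	1.767	-2.098	1.869	1.488	1.137	-1.618	-0.627	-0.531
g003	-0.125	-0.093	-0.798	0.539	2.417	0.137	-1.066	-0.424	-0.732	2.112	0.651	-0.252
g004	-0.384	-1.597	0.754	1.081	0.938	2.276	-2.086	-0.402	0.045	-0.496	1.352	0.832
g005	0.562	-0.045	1.254	0.305	1.416	0.87	-0.703	0.676	2.837	-0.673	0.396	-0.123
g006	1.373	-0.009	-1.613	0.29	0.69	-0.551	2.861	-0.105	-2.09	-0.533	1.711	0.335
g007	0.654	1.21	0.282	-0.372	-1.625	-0.665	-1.212	-2.127	-1.7	-0.164	0.314	-0.382
g008	-2.184	1.178	3.547	-0.664	1.154	1.582	-1.16	-1.076	-0.249	1.359	0.26	2.198
g009	-1.001	-0.039	0.932	-0.51	1.07	0.744	-0.417	1.381	-0.809	0.943	-2.568	-0.729
g010	0.399	-0.139	-1.357	-0.345	-0.816	0.006	-0.559	0.866	-0.374	-1.171	-0.166	-1.131
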