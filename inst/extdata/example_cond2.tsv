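gene	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10	s11	s12
g001	-1.662	1.647	-1.211	0.472	1.007	0.389	0.201	-0.322	-1.105	0.293	1.331	0.573
g002	-1.045	0.539	-0.541	0.841	-1.867	0.674	0.666	0.622	0.814	1.082	0.862	-2.229
g003	-0.458	-0.717	0.087	-0.559	0.021	-0.343	1.382	0.043	2.386	-0.046	-0.838	0.39
g004	-1.307	0.32	1.54	1.266	-1.166	1.05	-0.237	-0.551	-0.016	-0.289	0.343	-0.419
g005	0.137	-0.638	0.163	-0.786	-0.091	-1.932	1.571	-0.962	1.619	-1.312	-0.791	0.348
g006	-1.363	1.044	-0.493	-0.362	1.059	0.033	-0.946	1.806	0.941	2.034	-0.893	-0.721
g007	0.821	0.468	1.62	0.389	0.781	1.144	0.896	-0.106	-1.189	-0.25	-0.553	0.186
g008	0.75	-1.489	2.251	0.917	-0.167	-0.003	-1.106	0.023	-0.082	-0.367	0.373	-1.075
g009	0.212	1.616	0.914	1.413	0.589	1.719	0.131	-0.798	-0.564	1.614	-0.642	1.376
g010	2.434	-0.633	-0.682	-0.506	0.024	-1.141	1.596	-1.204	1.134	2.535	-0.186	0.834
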