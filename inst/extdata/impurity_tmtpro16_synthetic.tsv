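channel	126	127N	127C	128N	128C	129N	129C	130N	130C	131N	131C	132N	132C	133N	133C	134N
126	0.9592	0.015	0.001	0	0	0	0	0	0	0	0	0	0	0	0	0
127N	0.024	0.9588	0.0165	0.0011	0	0	0	0	0	0	0	0	0	0	0	0
127C	0.0022	0.023	0.9583	0.018	0.0012	0	0	0	0	0	0	0	0	0	0	0
128N	0	0.002	0.022	0.9539	0.012	0.001	0	0	0	0	0	0	0	0	0	0
128C	0	0	0.0022	0.025	0.9606	0.0135	0.0011	0	0	0	0	0	0	0	0	0
129N	0	0	0	0.002	0.024	0.9605	0.015	0.0012	0	0	0	0	0	0	0	0
129C	0	0	0	0	0.0022	0.023	0.9597	0.0165	0.001	0	0	0	0	0	0	0
130N	0	0	0	0	0	0.002	0.022	0.9553	0.018	0.0011	0	0	0	0	0	0
130C	0	0	0	0	0	0	0.0022	0.025	0.9548	0.012	0.0012	0	0	0	0	0
131N	0	0	0	0	0	0	0	0.002	0.024	0.9619	0.0135	0.001	0	0	0	0
131C	0	0	0	0	0	0	0	0	0.0022	0.023	0.9611	0.015	0.0011	0	0	0
132N	0	0	0	0	0	0	0	0	0	0.002	0.022	0.957	0.0165	0.0012	0	0
132C	0	0	0	0	0	0	0	0	0	0	0.0022	0.025	0.9562	0.018	0.001	0
133N	0	0	0	0	0	0	0	0	0	0	0	0.002	0.024	0.9558	0.012	0.0011
133C	0	0	0	0	0	0	0	0	0	0	0	0	0.0022	0.023	0.9628	0.0135
134N	0	0	0	0	0	0	0	0	0	0	0	0	0	0.002	0.022	0.9584
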