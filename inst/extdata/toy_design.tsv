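channel	sample_id	group	sex	hypertension
126	S01	young	female	0
127N	S02	young	female	0
127C	S03	young	female	0
128N	S04	young	male	0
128C	S05	young	male	0
129N	S06	young	male	0
129C	S07	young	male	0
130N	S08	young	male	0
130C	S09	old	female	1
131N	S10	old	female	1
131C	S11	old	female	1
132N	S12	old	female	1
132C	S13	old	male	0
133N	S14	old	male	0
133C	S15	old	male	0
134N	S16	old	male	0
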