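sequence	protein	interference	reporter_126	reporter_127N	reporter_127C	reporter_128N	reporter_128C	reporter_129N	reporter_129C	reporter_130N	reporter_130C	reporter_131N	reporter_131C	reporter_132N	reporter_132C	reporter_133N	reporter_133C	reporter_134N
AAAAAAK	P1	0	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
CCCCCCK	P1	0.1	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
DDDDDDK	P1	0.3	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
EEEEEEK	P1	0.5	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
FFFFFFK	P2	0.2					100	100	100	100	100	100	100	100	100	100	100	100
GGGGGGK	P2	0.4					100	100	100	100	100	100	100	100	100	100	100	100
HHHHHHK	P2	0.45					100	100	100	100	100	100	100	100	100	100	100	100
IIIIIIK	P3	0.51	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
LLLLLLK	P3	0.6	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
MMMMMMK	P4	0	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	
NNNNNNK	P4	0.55	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
QQQQQQK	P4	1	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100	100
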