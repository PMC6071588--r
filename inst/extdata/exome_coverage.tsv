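family	individual	relationship	degree	coverage
A	III-4	proband	0	91X
A	III-5	sister	1	51X
A	III-1	half cousin	4	51X
A	II-4	aunt	2	68X
B	IV-3	proband	0	36X
B	IV-5	cousin	3	77X
B	II-2	grandmother	2	63X
C	IV-1	proband	0	49X
C	III-6	first cousin once removed	4	52X
C	IV-2	second cousin	5	38X
D	III-1	proband	0	52X
D	III-5	cousin	3	44X
D	II-5	aunt	2	49X
E	IV-1	proband	0	55X
E	III-3	aunt	2	40X
E	II-3	great aunt	3	38X
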