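#n=10
#folded=0
locus1	2000	68	18	8	9	1	3	2	2	0	1
locus2	3000	40	15	5	3	2	3	2	2	0	3
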