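label	n	area	lineage	p3	p6	p9	p12	p15	p18	p21	p24	printed_mlCOIintF	printed_LerayXT
#I	11	North Sea, Mediterranean	NA (North Atlantic)	C	A	T	A	T	T	C	C	1	1
#II	89	Arctic Ocean, Norwegian Sea	ARK (Arctic)	T	A	T	G	T	G	C	C	2	0
#III	75	Southern Ocean	ANT (Antarctic)	T	C	T	A	T	G	C	T	2	1
#IV	6	Southern Ocean	AS (Amundsen Sea)	T	G	T	A	T	T	C	A	2	2
#V	28	Southern Ocean	PF (Polar Front)	C	A	T	A	T	G	T	A	3	2
#VI	1	Southern Ocean	PF (Polar Front)	T	T	T	A	T	G	C	T	1	0
#VII	1	Arctic Ocean	ARK2 (Arctic: Chukchi Plateau)	G	T	C	A	G	A	C	A	4	4
#VIII	1	Arctic Ocean	ARK3 (Arctic: Chukchi Plateau)	T	A	T	A	T	G	T	C	1	0
#IX	1	Arctic Ocean	ARK (Arctic: Greenland Sea)	T	G	T	G	T	G	C	C	3	1
#X	5	Beagle Channel (Argentina)	BC (Beagle Channel)	C	A	T	G	T	G	C	C	3	1
#XI	4	Canada (Pacific Ocean), California	New sequences, from MZGdb	G	G	C	G	A	G	C	A	6	4
#XII	4	Canada (Hudson Bay), North Sea	New sequences, from MZGdb	C	T	T	G	T	T	C	G	3	2
#XIII	20	Pacific Ocean (China, Korea and 1 N/A)	NP (North Pacific)	T	A	T	G	A	G	T	C	2	0
#XIV	1	N/A (probably Korea)	New sequences, from MZGdb	C	A	T	G	A	A	T	C	2	1
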