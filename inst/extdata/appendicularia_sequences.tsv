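accession	species	p1	p3	p4	p5	p6	p7	p9	p12	p15	p16	p18	p22	p23	p24	printed_mlCOIintF	printed_LerayXT	polyt
SCLE01415711	Bathochordaeus stygius	A		T			A		G		A				A	6	3	no
SCLF01725989	Mesochordaeus erythrocephalus	A		T			A	G	G		A					6	3	no
PP339655	Megalocercus abyssorum	A		T		C	A	G	G		A					7	4	no
LC222754	Oikopleura longicauda			T			A	G	G		A					5	2	no
SCLD01101138	Oikopleura longicauda			T			A	G	G		A					5	2	no
PP339656	Oikopleura longicauda			T					G		A					3	1	no
PP339657	Oikopleura longicauda		C	T					G	C	A				A	6	4	no
PP339658	Oikopleura longicauda	A		T					G		A					4	2	no
PP339659	Oikopleura fusiformis		C	T					G	G	A	G	G	T		8	5	no
SAMN00177767	Oikopleura dioica	A		T			A		G	C	A					6	3	yes
PP339660	Oikopleura dioica	A		T			A			C	A					5	3	yes
GCJN01047493	Oikopleura dioica	A		T					G		A					4	2	yes
PP339661	Oikopleura albicans		G	T			A		G			G				5	2	yes
PP339662	Stegosoma magnum	A		T			A		G		A	C				6	2	yes
PP339663	Appendicularia sicula	A														1	1	yes
PP339664	Fritillaria borealis sargassi	A									T	G				3	1	yes
PP339665	Fritillaria pellucida	A	G				A				T				A	5	3	yes
PP339666	Fritillaria formica tuberculata	A		T	G											3	3	yes
PP339667	Kowalevskia tenuis	A	G	G	G	G		G			T					7	6	no
PP339668	Kowalevskia oceanica	A		G	G	G										4	4	no
PP339669	Kowalevskia oceanica	A		G	G	G										4	4	no
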