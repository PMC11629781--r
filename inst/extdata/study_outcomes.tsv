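study_code	taxon	taxon_group	ocean_basin	primer_combination	outcome
1	Appendicularians	tunicate	AO	Leray-Geller	NA
2	Appendicularians	tunicate	PO	Leray-Geller	fail
3	Appendicularians	tunicate	AO	Leray-Geller	fail
4	Appendicularians	tunicate	AO	Leray-Geller	NA
5	Appendicularians	tunicate	AO	Leray-Geller	NA
6	Appendicularians	tunicate	AO	Leray XT	NA
7	Appendicularians	tunicate	SO	Leray XT	fail
8	Appendicularians	tunicate	AO	Leray-Folmer	fail
9	Appendicularians	tunicate	AO	Leray XT	fail
9	Appendicularians	tunicate	ArO	Leray XT	fail
10	Appendicularians	tunicate	AO	Leray XT	fail
11	Appendicularians	tunicate	PO	Leray-Folmer	fail
12	Appendicularians	tunicate	PO	Leray-Geller	NA
13	Appendicularians	tunicate	PO	Leray-Geller	NA
14	Appendicularians	tunicate	PO	Leray-Geller	fail
15	Appendicularians	tunicate	PO	Leray-Geller	fail
16	Appendicularians	tunicate	PO	Leray-Geller	NA
17	Appendicularians	tunicate	PO	Leray-Geller	fail
18	Appendicularians	tunicate	PO	Leray-Geller	fail
19	Appendicularians	tunicate	PO	Leray-Geller	fail
20	Appendicularians	tunicate	AO	Leray-Meyer	NA
21	Appendicularians	tunicate	AO	Leray-Geller	bias
22	Appendicularians	tunicate	PO	Leray-Geller	NA
23	Appendicularians	tunicate	IO	Leray-Geller	NA
24	Appendicularians	tunicate	ArO	Leray-Geller	NA
25	Appendicularians	tunicate	AO	Other	fail
26	Appendicularians	tunicate	IO	Leray-Folmer	NA
27	Appendicularians	tunicate	AO	Other	fail
28	Appendicularians	tunicate	ArO	Other	NA
29	Appendicularians	tunicate	AO	Leray-Meyer	fail
30	Appendicularians	tunicate	Undet.	Other	fail
1	Oithona similis	copepod	AO	Leray-Geller	NA
2	Oithona similis	copepod	PO	Leray-Geller	NA
3	Oithona similis	copepod	AO	Leray-Geller	NA
4	Oithona similis	copepod	AO	Leray-Geller	NA
5	Oithona similis	copepod	AO	Leray-Geller	NA
6	Oithona similis	copepod	AO	Leray XT	OK
7	Oithona similis	copepod	SO	Leray XT	OK
8	Oithona similis	copepod	AO	Leray-Folmer	fail
9	Oithona similis	copepod	AO	Leray XT	OK
10	Oithona similis	copepod	AO	Leray XT	OK
11	Oithona similis	copepod	PO	Leray-Folmer	fail
12	Oithona similis	copepod	PO	Leray-Geller	OK
13	Oithona similis	copepod	PO	Leray-Geller	NA
14	Oithona similis	copepod	PO	Leray-Geller	fail
15	Oithona similis	copepod	PO	Leray-Geller	fail
16	Oithona similis	copepod	PO	Leray-Geller	OK
17	Oithona similis	copepod	PO	Leray-Geller	NA
18	Oithona similis	copepod	PO	Leray-Geller	fail
19	Oithona similis	copepod	PO	Leray-Geller	fail
20	Oithona similis	copepod	AO	Leray-Meyer	NA
21	Oithona similis	copepod	AO	Leray-Geller	NA
22	Oithona similis	copepod	PO	Leray-Geller	NA
23	Oithona similis	copepod	IO	Leray-Geller	NA
24	Oithona similis	copepod	ArO	Leray-Geller	NA
25	Oithona similis	copepod	AO	Other	bias
26	Oithona similis	copepod	IO	Leray-Folmer	NA
27	Oithona similis	copepod	AO	Other	OK
28	Oithona similis	copepod	ArO	Other	OK
29	Oithona similis	copepod	AO	Leray-Meyer	bias
30	Oithona similis	copepod	Undet.	Other	OK
9	Acartia spp.	copepod	AO	Leray XT	bias
9	Acartia spp.	copepod	ArO	Leray XT	bias
10	Acartia spp.	copepod	AO	Leray XT	bias
11	Acartia spp.	copepod	PO	Leray-Folmer	bias
14	Acartia spp.	copepod	PO	Leray-Geller	bias
15	Acartia spp.	copepod	PO	Leray-Geller	bias
6	Microsetella norvegica	copepod	AO	Leray XT	bias
9	Microsetella norvegica	copepod	AO	Leray XT	bias
9	Microsetella norvegica	copepod	ArO	Leray XT	bias
30	Microsetella norvegica	copepod	Undet.	Other	fail
14	Paracalanus spp.	copepod	PO	Leray-Geller	bias
15	Paracalanus spp.	copepod	PO	Leray-Geller	bias
30	Calanus finmarchicus	copepod	Undet.	Other	fail
25	Calocalanus styliremis	copepod	AO	Other	fail
20	Centropages spp.	copepod	AO	Leray-Meyer	bias
12	Cyclopoida	copepod	PO	Leray-Geller	bias
10	Detrichocoryceaus spp.	copepod	AO	Leray XT	bias
9	Metridia spp.	copepod	AO	Leray XT	bias
9	Metridia spp.	copepod	ArO	Leray XT	bias
24	Microcalanus pygmaeus	copepod	ArO	Leray-Geller	fail
30	Oithona atlantica	copepod	Undet.	Other	fail
25	Oithona nana	copepod	AO	Other	fail
17	Oithonids	copepod	PO	Leray-Geller	fail
29	Oncaea spp.	copepod	AO	Leray-Meyer	bias
10	Oncaeidae	copepod	AO	Leray XT	bias
30	Pseudocalanus mimus	copepod	Undet.	Other	fail
20	Temora spp.	copepod	AO	Leray-Meyer	bias
30	Oikopleura labradoriensis	tunicate	Undet.	Other	fail
3	Doliolida	tunicate	AO	Leray-Geller	fail
17	Doliolida	tunicate	PO	Leray-Geller	fail
18	Doliolida	tunicate	PO	Leray-Geller	fail
29	Doliolida	tunicate	AO	Leray-Meyer	fail
17	Pyrosomata	tunicate	PO	Leray-Geller	fail
18	Pyrosomata	tunicate	PO	Leray-Geller	fail
19	Pyrosomata	tunicate	PO	Leray-Geller	fail
3	Salpida	tunicate	AO	Leray-Geller	fail
18	Salpida	tunicate	PO	Leray-Geller	fail
19	Salpida	tunicate	PO	Leray-Geller	fail
14	Chaetognatha	other	PO	Leray-Geller	fail
16	Chaetognatha	other	PO	Leray-Geller	bias
2	Ctenophora	other	PO	Leray-Geller	fail
20	Mertensia spp.	other	AO	Leray-Meyer	fail
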