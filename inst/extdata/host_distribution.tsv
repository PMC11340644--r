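order	n	Chordata	Invertebrate	Viridiplantae	Fungi	Bacteria	Primates	Rodentia	Carnivora	Artiodactyla	Chiroptera	Other Mammalia	Aves	Reptilia	Amphibia	Fish	Mammalia
Ortervirales	2764	92.0	NA	8.0	NA	NA	85.9	0.9	0.9	2.0	NA	0.7	1.6	NA	NA	NA	NA
Picornavirales	2647	74.2	12.2	13.6	NA	NA	40.2	4.1	4.2	14.5	2.6	1.7	3.9	0.9	NA	2.0	NA
Bunyavirales	1524	52.4	31.6	15.2	0.9	NA	18.0	17.6	NA	1.6	1.4	5.3	1.7	5.6	NA	1.2	NA
Tymovirales	1042	NA	2.6	94.3	3.1	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Reovirales	1034	52.9	33.8	9.7	3.6	NA	9.9	1.3	2.9	9.0	5.5	3.6	9.6	1.3	NA	10.0	NA
Amarillovirales	817	85.2	14.8	NA	NA	NA	54.0	9.7	NA	10.0	4.0	4.2	1.7	NA	NA	1.6	NA
Mononegavirales	758	57.5	27.8	11.3	3.3	NA	11.3	6.5	4.0	5.4	11.5	2.4	9.0	1.6	NA	5.9	NA
Martellivirales	670	5.1	6.3	73.7	14.9	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	5.1
Nidovirales	622	94.4	5.6	NA	NA	NA	4.8	5.3	5.6	36.3	17.4	5.6	13.5	5.8	NA	NA	NA
Patatavirales	558	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Ghabrivirales	393	NA	14.0	9.9	76.1	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Durnavirales	340	5.0	NA	32.4	62.6	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	5.0
Stellavirales	296	100.0	NA	NA	NA	NA	10.1	12.8	8.4	33.1	5.1	NA	16.2	NA	4.4	9.8	NA
Tolivirales	226	NA	15.0	73.9	11.1	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Hepelivirales	181	80.1	10.5	9.4	NA	NA	32.0	16.6	NA	16.6	NA	8.8	6.1	NA	NA	NA	NA
Sobelivirales	120	NA	12.5	87.5	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Blubervirales	108	100.0	NA	NA	NA	NA	75.9	NA	NA	NA	14.8	NA	9.3	NA	NA	NA	NA
Cryppavirales	80	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Articulavirales	77	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	16.9	NA	NA	23.4	59.7
Jingchuvirales	61	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Nodamuvirales	42	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Ourlivirales	38	NA	NA	26.3	73.7	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Wolframvirales	23	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Mindivirales	22	NA	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Norzivirales	21	NA	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Serpentovirales	16	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Muvirales	9	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Yadokarivirales	7	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Goujianvirales	3	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
Timlovirales	1	NA	NA	NA	NA	100.0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
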