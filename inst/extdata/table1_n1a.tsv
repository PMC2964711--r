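haplogroup	hvs1_motif	hvs2_motif	n	population	region	source
N1a	147G-172-223-248		1	Turkey	Near East	R3
N1a	147G-172-223-248-355		1	Yemen	Near East	R24
N1a	147G-172-223-248-355		5	Ethiopia	Africa	R3
N1a	147G-172-223-248-355		2	Tanzania	Africa	R3
N1a	147G-172-223-248-355	151-199-204	2	Arabia Peninsula	Near East	R20
N1a	147G-172-223-248-355	151-199-204	1	Saudi Arabia	Near East	R23
N1a	147G-172-223-248-355	199-204	1	Arabia Peninsula	Near East	R20
N1a	147G-172-223-248-355	199-204	1	Dubai-Arabia	Near East	R26
N1a	147G-172-223-248-355	194-199-204	1	Bedouin-Israel	Near East	R25
N1a	147G-172-223-248-355	152-199-204	1	Greece	Europe	R27
N1a	147G-172-223-248-355	152-199-204	1	Russia	Eastern Europe	R19
N1a	147G-172-223-224-248-355-357		1	Greece	Europe	R3
N1a	147G-172-223-248-260-355		1	Ethiopia	Africa	R3
N1a	147G-223-248-263-266-355		2	Yemen	Near East	R3
N1a	147G-172-223-248-263-266-355		1	Yemen	Near East	R3
N1a	147G-172-213-223-248-355		1	Somali	Africa	R3
N1a	147G-172-213-223-248-291-355	146-152-182-185C	1	Ethiopia	Africa	R25
N1a	124-147G-172-213-223-248-355		1	Yemen	Near East	R3
N1a	147G-172-223-248-295-355		3	India - South West	South Asia	R3
N1a	147G-172-209-223-248-295-355		2	India - South West	South Asia	R3
N1a	147G-172-223-248-295-297-355		1	Kabardian, North Caucasus	Caucasus	R3
N1a	147G-172-223-248-295-297-344-355		1	Turkey	Near East	R3
N1a	147G-172-223-248-295-344-355		1	Iran	Near East	R13
N1a1a1	172-223-248-320-355		1	Lithunia	Eastern Europe	R14
N1a1a1	147A-172-248-320-355		1	Poland	Europe	R3
N1a1a1	147A-172-223-248-320		1	Estonia	Eastern Europe	R3
N1a1a1	147A-172-223-248-320		1	Tatar	Eastern Europe	R3
N1a1a1	147A-172-223-248-320-355		2	Yemen	Near East	R3
N1a1a1	147A-172-223-248-320-355		1	Turkmenistan	Central Asia	R3
N1a1a1	147A-172-223-248-320-355		1	Iran	Near East	R13
N1a1a1	147A-172-223-248-320-355		1	Kazakhstan	Central Asia	R16
N1a1a1	147A-172-223-248-320-355		2	Russia	Eastern Europe	R3
N1a1a1	147A-172-223-248-320-355		1	Estonia	Eastern Europe	R14
N1a1a1	147A-172-223-248-320-355		5	Estonia	Eastern Europe	R3
N1a1a1	147A-172-223-248-320-355		1	Lithunia	Eastern Europe	R14
N1a1a1	147A-172-223-248-320-355		1	Iran	Near East	R3
N1a1a1	147A-172-223-248-320-355		1	Slovakia	Europe	R3
N1a1a1	147A-172-223-248-320-355	152-199-204	1	Tatar-Russia	Eastern Europe	Present study (9)
N1a1a1	147A-172-223-248-320-355	152-199-204	1	Russia	Eastern Europe	Present Study (10)
N1a1a1	147A-172-223-248-320-355	152-199-204	1	Slovakia	Europe	R15
N1a1a1	147A-172-223-248-320-355	152-199-204	1	Altai Republic	South Siberia	R9
N1a1a1	147A-172-223-248-320-355	152-199-204	3	Finland	Eastern Europe	R14
N1a1a1	147A-172-223-248-320-355	152-199-204	2	India	South Asia	Present study (8)
N1a1a1	147A-172-223-248-320-355	151-152-199-204	1	India	South Asia	Present study (7)
N1a1a1	147A-172-223-248-291-320-355		1	Egypt	Africa	R3
N1a1a1	147A-172-223-248-294-320-355		1	Estonia	Eastern Europe	R3
N1a1a1	147A-172-223-248-294-320-355		1	India - South East	South Asia	R3
N1a1a1	147A-172-223-248-295-320-355		1	Buryat Republic	South Siberia	R3
N1a1a1	147A-172-209-223-248-320-355		2	Croation-Italian	Europe	R3
N1a1a1	147A-172-206-223-248-320-355		1	France	Europe	R3
N1a1a1	147A-172-195-223-248-320-355		1	Germany	Europe	R3
N1a1a1	114A-147A-172-223-248-320-325-355		1	Germany	Europe	R3
N1a1a1	93-147A-169-172-193iC-223-248-320-355		1	Russia	Eastern Europe	R12
N1a1a1a	147A-189-223-248-272-320-355		1	Russia	Eastern Europe	R3
N1a1a1a	147A-172-189-223-248-320-355		1	Russia	Eastern Europe	R17
N1a1a1a	147A-172-189-223-248-320-355		1	Russia	Eastern Europe	R18
N1a1a1a	147A-172-189-223-248-320-355		5	Kazakhstan	Central Asia	R16
N1a1a1a	147A-172-189-223-248-320-355		1	Hungary	Europe	R3
N1a1a1a	147A-172-189-223-248-320-355		6	Russia	Eastern Europe	R3
N1a1a1a	147A-172-189-223-248-320-355		3	Altai Republic	South Siberia	R3
N1a1a1a	147A-172-189-223-248-320-355		1	Kalmyks	Eastern Europe	R3
N1a1a1a	147A-172-189-223-248-320-355		5	Kazakhs	Central Asia	R3
N1a1a1a	147A-172-189-223-248-320-355		3	Turkey	Near East	R3
N1a1a1a	147A-172-189-223-248-320-355		1	Hungary	Europe	R3
N1a1a1a	147G-172-189-223-248-320-355		1	Altai Republic	South Siberia	R3
N1a1a1a	147A-172-189-223-248-270-320-355		1	Lithunia	Eastern Europe	R14
N1a1a1a	147A-172-189-223-248-272-320-355		4	Russia	Eastern Europe	R3
N1a1a1a	147A-172-183C-189-223-248-320-355		1	Buryat Republic	South Siberia	R3
N1a1a1a	147A-172-189-193iC-223-248-320-355	152-199-204	1	Poland	Europe	R19
N1a1a1a	147A-172-189-193iC-223-248-320-355	152-199-204	1	Ulaanbaatar	South Siberia	R9
N1a1a1a	147A-172-189-193iC-223-248-320-355	152-199-204	1	Buryat Republic	South Siberia	R9
N1a1a1a	147A-172-189-193iC-223-248-320-355	143-146-152-199	1	Kazakh-South Siberia	South Siberia	Present study (1)
N1a1a1a	147A-172-189-193iCC-223-248-320-355	146-152-199-204	1	Hungary	Europe	Present study (2)
N1a1a1a	147A-172-187A-189-223-248-320-355		1	Russia	Eastern Europe	R3
N1a1a1a	147A-172-181-189-223-248-320-355		1	Kazakhstan	Central Asia	R16
N1a1a2	147A-223-248-320-355		1	France	Europe	R3
N1a1a2	147A-223-248-320-355	152-199-204-207	1	United States of America	North America	Present Study (14)
N1a1a2	147A-172-223-248-320-355	152-199-204-207	1	Poland	Europe	R19
N1a1a2	86-147A-223-320-355		1	Switzerland	Europe	R3
N1a1a2	86-147A-223-248-320-355	152-199-204-207	1	Arizona	North America	Present Study (11)
N1a1a2	86-147A-223-248-320-355		3	Switzerland	Europe	R3
N1a1a2	86-147A-223-248-320-355	152-199-204-207	1	Austria	Europe	R21
N1a1a2	86-147A-189-223-248-320-355		1	Denmark	Europe	R3
N1a1a2	86-147A-189-193iCC-223-248-320-355	152-199-204-207	1	France	Europe	Present Study (12)
N1a1a2	86-147A-223-248-319-320-355		1	Scotland	Europe	R3
N1a1a2	86-147A-223-248-320-324-355		1	Acores-Portugal	Europe	R3
N1a1a2	86-147A-223-248-278-320-355		6	Russia	Eastern Europe	R3
N1a1a2	86-147A-223-248-278-320-355		1	Udmurts	Eastern Europe	R3
N1a1a2	86-147A-148-214-223-320-355		1	Norway	Europe	R3
N1a1a2	86-147A-172-223-248-320-355		1	Portugal	Europe	R22
N1a1a2	86-147A-172-223-248-320-325-355	152-199-204-207	1	Arabia Peninsula	Near East	R20
N1a1a2	86-147A-164-172-223-248-320-355		1	France	Europe	R3
N1a1a2	86-147A-164-172-223-248-320-355		1	Portugal	Europe	R3
N1a1a2	86-147A-164-172-223-248-320-355		1	Hungary	Europe	R3
N1a1a2	86-147A-150-164-172-209-223-248-320-355-463	152-199-204-207	1	New Mexico	North America	Present Study
N1a1a3	147A-154-172-223-320-355	152-199-204	1	Austria	Europe	R21
N1a1a3	147A-154-172-223-320-355		1	Sweden	Europe	R3
N1a1a3	147A-154-172-223-320-355		1	Slovakia	Europe	R3
N1a1a3	147A-154-172-223-320-355	152-199-203-204	1	Slovakia	Europe	R15
N1a1a3	147A-154-172-223-248-258-320-355	152-199-204	1	Arabia Peninsula	Near East	R20
N1a1a3	147A-154-170-172-223-248-320-355		2	Yemen	Near East	R3
N1a1a3	92-129-147A-154-172-223-248-320-355	143-152-182-199-204-234	1	South Carolina	North America	Present Study (15)
N1a1a3	92-129-147A-154-172-223-248-320-355	143-152-199-204-234	1	Russia	Eastern Europe	Present Study (16)
N1a1a3	92-129-147A-154-172-223-248-320-355		1	Molise-Italy	Europe	R3
N1a1a3	92-129-147A-154-172-223-248-320-355		1	Norway	Europe	R3
N1a1a3	92-129-147A-154-172-223-248-320-355		1	Germany	Europe	R3
N1a1b	147A-172-223-248-355		1	Setoland	Eastern Europe	R14
N1a1b	147A-172-223-248-355		1	Egypt	Africa	R3
N1a1b	147A-172-223-248-355		1	Armenia	Caucasus	R3
N1a1b	93-147A-172-223-248-355	199-204	1	Italy	Europe	Present Study (17)
N1a1b	147A-172-223-245-248-355	183-199-204	1	Arabia Peninsula	Near East	R20
N1a1b	147A-172-189-223-248-355	199-204	1	Arabia Peninsula	Near East	R20
N1a1b	147A-172-223-248-266-274-355	199-204	1	Arabia Peninsula	Near East	R20
N1a1b	147A-172-218-223-248-261-274-355	41-199-204	1	Arabia Peninsula	Near East	R20
N1a1b	147A-172-218-223-248-261-274-355	41-199-204	4	Saudi Arabia	Near East	R23
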