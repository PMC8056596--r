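5	137574148	139574148	5q35_deletion
1	65532789	67532789	1q43q44_deletion
9	142119145	144119145	9q21.32_deletion
6	108655207	110655207	6q_proximal_deletion
4	68085365	70085365	4q21_microdeletion
1	1796708	3796708	1p36_monosomy
12	302617163	303617163	GD01
8	395395738	396395738	GD02
4	377199448	378199448	GD03
21	352451033	353451033	GD04
2	361222442	362222442	GD05
5	395892893	396892893	GD06
13	319641237	320641237	GD07
7	311052713	312052713	GD08
7	321129058	322129058	GD09
2	382421719	383421719	GD10
22	317067588	318067588	GD11
7	391723849	392723849	GD12
14	389922423	390922423	GD13
9	335456183	336456183	GD14
1	379908396	380908396	GD15
20	395387993	396387993	GD16
19	329258459	330258459	GD17
13	332342721	333342721	GD18
22	322575576	323575576	GD19
8	322000891	323000891	GD20
14	388153470	389153470	GD21
4	305839043	306839043	GD22
3	343029314	344029314	GD23
14	319342831	320342831	GD24
1	338116045	339116045	GD25
14	329451189	330451189	GD26
8	325924516	326924516	GD27
10	364025745	365025745	GD28
20	359185810	360185810	GD29
20	358508686	359508686	GD30
4	372972249	373972249	GD31
7	321242306	322242306	GD32
19	365275372	366275372	GD33
5	347171448	348171448	GD34
18	324305117	325305117	GD35
17	319001972	320001972	GD36
14	308512679	309512679	GD37
7	343447665	344447665	GD38
4	353710480	354710480	GD39
2	367810345	368810345	GD40
19	344130687	345130687	GD41
6	318152139	319152139	GD42
7	353083869	354083869	GD43
10	336909674	337909674	GD44
15	354493691	355493691	GD45
6	301704517	302704517	GD46
22	326340041	327340041	GD47
20	347173127	348173127	GD48
17	345848337	346848337	GD49
13	341123386	342123386	GD50
21	309812549	310812549	GD51
6	350845740	351845740	GD52
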