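17	65354449	65404449	HNRNPA0
5	148088899	148138899	HNRNPA1
1	149965879	150015879	HNRNPA2B1
10	199656726	199706726	HNRNPA3
4	62910260	62960260	HNRNPAB
18	195626161	195676161	HNRNPC
17	18160581	18210581	HNRNPCL1
15	9471923	9521923	HNRNPCL4
4	68285365	68335365	HNRNPD
4	67467685	67517685	HNRNPDL
5	180909257	180959257	HNRNPF
5	137774148	137824148	HNRNPH1
20	3130864	3180864	HNRNPH2
18	7722787	7772787	HNRNPH3
9	142319145	142369145	HNRNPK
3	89655516	89705516	HNRNPL
9	5930515	5980515	HNRNPLL
4	118970410	119020410	HNRNPM
1	1996708	2046708	HNRNPR
1	65732789	65782789	HNRNPU
5	128350640	128400640	HNRNPUL1
20	60896132	60946132	HNRNPUL2
6	108855207	108905207	SYNCRIP
8	197512039	197562039	PTBP1
3	10739235	10789235	PTBP2
1	105382563	105432563	PCBP1
10	66440041	66490041	PCBP2
11	161497754	161547754	PCBP3
15	186375924	186425924	RALY
22	71605650	71655650	RALYL
8	154064143	154114143	RBMX
4	117766779	117816779	RBMXL2
4	86781328	86831328	FUS
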