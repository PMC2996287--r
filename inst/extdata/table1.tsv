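no	label	T	M	alpha	lambda_asym	lambda_num	lambda_emp
1	Moby Dick (English)	206779	18217	1.323	0.756	0.725	0.738
2	De Bello Gallico (Latin)	20516	5671	0.969	1	0.858	0.859
3	Principia Mathematica (Latin)	109854	13906	1.063	0.941	0.845	0.817
4	Don Quijote (Spanish)	449205	20220	1.464	0.683	0.667	0.679
5	La Celestina (Spanish)	68458	9191	1.095	0.913	0.823	0.810
6	Faust (German)	81037	13254	1.025	0.976	0.859	0.832
7	Aeneis (Latin)	63742	16622	1.057	0.946	0.840	0.852
8	Cien anos de soledad (Spanish)	138985	15550	1.188	0.842	0.787	0.765
9	La Divina Commedia (Italian)	101940	12667	1.117	0.895	0.818	0.799
10	PNAS keywords	504610	116800	0.893	1	0.936	0.863
11	Chin. Sci. Bull. keywords	53214	34194	0.540	1	0.983	0.946
12	J. Am. Chem. Soc. keywords	310853	69185	0.939	1	0.913	0.871
13	Acta Chim. Sinica keywords	30852	17562	0.595	1	0.972	0.939
14	Crit. Rev. Biochem. Mol. Biol. keywords	2761	2328	0.397	1	0.964	0.978
15	J. Biochem. keywords	58300	22599	0.786	1	0.941	0.914
16	J. Nutr. Biochem. keywords	20660	8155	0.790	1	0.921	0.890
17	Phys. Rev. Lett. keywords	226090	69251	0.692	1	0.977	0.894
18	Appl. Phys. Lett. keywords	176291	62567	0.572	1	0.989	0.920
19	Physica A keywords	44735	19933	0.685	1	0.961	0.915
20	ACM Comput. Surv. keywords	1924	1323	0.463	1	0.946	0.939
21	ACM Trans. Graph. keywords	5093	2985	0.593	1	0.941	0.920
22	Comput. Netw. keywords	3490	2442	0.500	1	0.952	0.950
23	ACM Trans. Comput. Syst. keywords	1403	787	0.524	1	0.926	0.931
24	Econometrica keywords	7469	4142	0.654	1	0.936	0.925
25	J. Econ. Theo. keywords	7710	3857	0.658	1	0.935	0.930
26	SIAM Rev. keywords	3232	2658	0.416	1	0.964	0.976
27	SIAM J. Appl. Math. keywords	13165	7743	0.612	1	0.959	0.936
28	Invent. Math. keywords	3749	2353	0.568	1	0.943	0.940
29	Ann. Neurol. keywords	30092	11002	0.815	1	0.924	0.891
30	J. Evol. Biol. keywords	21894	8666	0.776	1	0.930	0.900
31	Theo. Popul. Biol. keywords	7627	3841	0.685	1	0.933	0.930
32	MIS Quart. keywords	4185	2242	0.675	1	0.921	0.929
33	IEEE Trans. Automat. Contr. keywords	23822	10753	0.648	1	0.959	0.917
34	H1N1 confirmed cases by country	8829	40	3.0	0.33	0.34	0.35
35	PNAS citation records	237982	56961	0.462	1	0.993	0.929
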