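strain	replicon	size_bp	gc_percent	n_orfs	rrna	trna	replication_class	chromid	essential_core_genes
CBG497	chromosome	2900071	68.4	2895	NA	42	oriC	FALSE	NA
CBG497	p1	1598241	68.8	1430	1	16	repABC	TRUE	40
CBG497	p2	731389	68.8	643	1	1	repABC	TRUE	6
CBG497	p3	488405	66.05	512	NA	2	repABC	FALSE	NA
CBG497	p4	606415	69.3	583	NA	6	repABC	TRUE	9
CBG497	p6	148687	67.1	122	0	0	repABC	FALSE	0
Sp245	chromosome	3023440	68.6	3309	2	44	oriC	FALSE	NA
Sp245	p1	1766028	68.6	1812	3	25	repABC	TRUE	NA
Sp245	p2	912449	68.3	922	2	2	repABC	TRUE	NA
Sp245	p3	778798	68.2	824	0	0	repABC	FALSE	NA
Sp245	p4	690334	69	691	1	9	repABC	TRUE	NA
Sp245	p5	191828	66.7	163	0	0	repABC	FALSE	NA
Sp245	p6	167364	66.8	125	0	1	repABC	FALSE	NA
4B	chromosome	2988332	67.6	2904	2	46	oriC	FALSE	NA
4B	p1	1040425	67.6	883	3	12	repABC	TRUE	NA
4B	p2	750123	67.6	640	2	5	repABC	TRUE	NA
4B	p3	648491	67.8	555	1	2	repABC	TRUE	NA
4B	p4	645253	68.3	599	0	6	repABC	TRUE	NA
4B	p5	478032	67.7	415	1	8	repABC	TRUE	NA
4B	p6	295744	67.1	237	0	0	repABC	FALSE	NA
B510	chromosome	3311395	67.8	3287	2	45	oriC	FALSE	NA
B510	p1	1455109	67.6	1263	4	14	repABC	TRUE	NA
B510	p2	723779	67.5	693	1	2	repABC	TRUE	NA
B510	p3	681723	67.4	589	1	3	repABC	TRUE	NA
B510	p4	628837	68	598	0	6	repABC	TRUE	NA
B510	p5	537299	67.5	464	1	9	repABC	TRUE	NA
B510	p6	261596	65.9	232	0	0	repABC	FALSE	NA
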