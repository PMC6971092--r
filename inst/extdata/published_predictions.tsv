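# Published table of 38 predicted emulsifier peptides from potato proteins
# (patatins and Kunitz-type protease inhibitors). score = printed z-score;
# separation = printed divide position for axial peptides; mw in g/mol.
peptide	score_type	sequence	score	separation	mw
alpha-10	alpha	KKPVSKDSPETYEEALKRFAKLLSDRKKL	2.176	NA	3405.9
alpha-11	alpha	EALKRFAKLLSD	3.522	NA	1390.6
alpha-12	alpha	DSPETYEEALKRFAKLLSD	3.037	NA	2212.4
alpha-13	alpha	NRPFAAAKDIVPFYFEHGPHIFN	2.155	NA	2688.0
alpha-14	alpha	AKDIVPFYFEHGPHIFN	2.255	NA	2031.3
alpha-15	alpha	IPATILEFLEGQLQEVDNN	2.000	NA	2143.4
alpha-16	alpha	ILEFLEGQLQEVDN	2.978	NA	1646.8
alpha-17	alpha	KYDGKYLMQVLQE	2.029	NA	1614.9
alpha-18	alpha	KYLMQVLQEKLGE	2.022	NA	1578.9
alpha-19	alpha	KYLMQVLQEKL	2.058	NA	1392.7
beta-20	beta	ELDSRLSYRIISTFWGALGGDVYLGKSPN	2.630	NA	3215.6
beta-21	beta	ELDSRLSYRIISTFWGALGGDVYL	3.131	NA	2732.0
beta-22	beta	CPFSSDDQFCLKVGV	2.501	NA	1644.9
beta-23	beta	FIPLSTNIFEDQLLNIQFNIPT	2.391	NA	2577.9
beta-24	beta	LNIQFNI	4.066	NA	861.0
beta-26	beta	GKELDPRLSYRI	2.218	NA	1446.7
beta-27	beta	LNIQFNIPTPKLC	2.213	NA	1500.8
beta-28	beta	VHQNGKRRLALVKDNPLDVSFK	2.056	NA	2534.9
beta-29	beta	IGSSSHFGPHIFEGELLNIQFDIS	2.027	NA	2644.9
beta-30	beta	DDNFCAKVGVVIQ	2.016	NA	1407.6
beta-31	beta	LGGDVYLGKSPNSDAPCP	2.011	NA	1789.9
gamma-1	gamma	GIKGIIPAIILEFLEGQLQEVDNNKDAR	4.146	14	3094.5
gamma-34	gamma	CRDDNFCAKVGVVI	3.387	5	1538.8
gamma-35	gamma	RDDNFCAKVGVVI	3.933	4	1435.7
gamma-36	gamma	FDVIGGTSTGGLLTAMITTPNENNRP	3.190	17	2676.9
gamma-37	gamma	LLTAMITTPNENNRP	4.037	6	1684.9
gamma-38	gamma	FCLKVGVVHQNGKRRLALVKDNP	3.168	8	2592.1
gamma-39	gamma	HQNGKRRLALV	4.790	7	1291.5
gamma-40	gamma	SSDDQFCLKVGVV	3.137	5	1396.6
gamma-41	gamma	KDNPETYEEALKRFAKLLS	3.066	13	2252.5
gamma-42	gamma	DTNGKELNPNSSYRIISIGRGALGGDVYL	3.055	14	3080.4
gamma-43	gamma	NPNSSYRIISI	3.401	7	1263.4
gamma-44	gamma	DNFCAKVGVVIQNGKRR	3.044	11	1904.2
gamma-45	gamma	VGVVIQNGKRR	4.779	5	1225.5
gamma-46	gamma	FAKLLSDRKKLRANK	3.043	5	1788.2
gamma-47	gamma	TPNENNRPFAAAKDIV	3.024	8	1756.9
gamma-48	gamma	GIIPATILEFLEGQLQEVDNN	3.003	11	2313.6
gamma-49	gamma	FCLKVGVIHQNGKRRLALVK	2.478	8	2279.8
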