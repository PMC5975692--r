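#! name: ASUC-CORE
#! version: both reversible  
#! objective: BIOMASS
rxn_id	equation	lb	ub	genes	ec	subsystem
GLCpts	glc__D_e + pep_c -> g6p_c + pyr_c	0	1000	(ptsG and ptsH and ptsI)	2.7.1.199	transport
GLCt2	glc__D_e + h_e -> glc__D_c + h_c	0	1000	gluP		transport
HEX1	glc__D_c + atp_c -> g6p_c + adp_c + h_c	0	1000	glk	2.7.1.2	glycolysis
SBTpts	sbt__D_e + pep_c -> sbt6p_c + pyr_c	0	1000	(srlA and srlB and srlE)	2.7.1.198	transport
S6PD	sbt6p_c + nad_c -> f6p_c + nadh_c + h_c	0	1000	srlD	1.1.1.140	alternate carbon
XYLt2	xyl__D_e + h_e -> xyl__D_c + h_c	0	1000	xylT		transport
XYLI	xyl__D_c <-> xylu__D_c	-1000	1000	xylA	5.3.1.5	alternate carbon
XYLK	xylu__D_c + atp_c -> x5p__D_c + adp_c + h_c	0	1000	xylB	2.7.1.17	alternate carbon
PGI	g6p_c <-> f6p_c	-1000	1000	pgi	5.3.1.9	glycolysis
PFK	f6p_c + atp_c -> fdp_c + adp_c + h_c	0	1000	pfkA	2.7.1.11	glycolysis
FBA	fdp_c <-> dhap_c + g3p_c	-1000	1000	fba	4.1.2.13	glycolysis
FBP	fdp_c + h2o_c -> f6p_c + pi_c	0	1000	fbp	3.1.3.11	glycolysis
TPI	dhap_c <-> g3p_c	-1000	1000	tpiA	5.3.1.1	glycolysis
GAPD	g3p_c + nad_c + pi_c <-> 13dpg_c + nadh_c + h_c	-1000	1000	gapA	1.2.1.12	glycolysis
PGK	13dpg_c + adp_c <-> 3pg_c + atp_c	-1000	1000	pgk	2.7.2.3	glycolysis
PGM	3pg_c <-> 2pg_c	-1000	1000	gpmA	5.4.2.12	glycolysis
ENO	2pg_c <-> pep_c + h2o_c	-1000	1000	eno	4.2.1.11	glycolysis
PYK	pep_c + adp_c + h_c -> pyr_c + atp_c	0	1000	pykA	2.7.1.40	glycolysis
GND	g6p_c + 2 nadp_c + h2o_c -> ru5p__D_c + co2_c + 2 nadph_c + 2 h_c	0	1000	(zwf and pgl and gnd)	1.1.1.49;1.1.1.44	pentose phosphate
RPE	ru5p__D_c <-> x5p__D_c	-1000	1000	rpe	5.1.3.1	pentose phosphate
TKTL	3 ru5p__D_c <-> 2 f6p_c + g3p_c	-1000	1000	(tktA and talB)	2.2.1.1;2.2.1.2	pentose phosphate
PPCK	pep_c + co2_c + adp_c -> oaa_c + atp_c	0	1000	pckA	4.1.1.49	C4 branch
MDH	oaa_c + nadh_c + h_c <-> mal__L_c + nad_c	-1000	1000	mdh	1.1.1.37	C4 branch
FUM	fum_c + h2o_c <-> mal__L_c	-1000	1000	(fumA or fumC)	4.2.1.2	C4 branch
FRDmq	fum_c + mql8_c -> succ_c + mqn8_c	0	1000	(frdA and frdB and frdC and frdD)	1.3.5.4	C4 branch
ME2	mal__L_c + nadp_c <-> pyr_c + co2_c + nadph_c	-1000	1000	maeB	1.1.1.40	C3-C4 bridge
OAADC	oaa_c + h_c -> pyr_c + co2_c	0	1000	oadA	4.1.1.3	C3-C4 bridge
PFL	pyr_c + coa_c -> accoa_c + for_c	0	1000	pflB	2.3.1.54	C3 branch
FDHmq	for_c + 3 h_c + mqn8_c -> co2_c + mql8_c + 2 h_e	0	1000	(fdhA and fdhB)	1.17.5.3	C3 branch
PTAr	accoa_c + pi_c <-> actp_c + coa_c	-1000	1000	pta	2.3.1.8	C3 branch
ACKr	actp_c + adp_c <-> ac_c + atp_c	-1000	1000	ackA	2.7.2.1	C3 branch
ACALD	accoa_c + nadh_c + h_c <-> acald_c + coa_c + nad_c	-1000	1000	adhE	1.2.1.10	C3 branch
ALCD2x	acald_c + nadh_c + h_c <-> etoh_c + nad_c	-1000	1000	adhE	1.1.1.1	C3 branch
NADHDH	nadh_c + 3 h_c + mqn8_c -> nad_c + mql8_c + 2 h_e	0	1000	(nuoA and nuoB)	1.6.5.3	respiration
ATPS4r	adp_c + pi_c + 4 h_e <-> atp_c + h2o_c + 3 h_c	-1000	1000	(atpA and atpB and atpC)	7.1.2.2	respiration
GLUDy	glu__L_c + h2o_c + nadp_c <-> akg_c + nh4_c + nadph_c + h_c	-1000	1000	gdhA	1.4.1.4	amino acids
ALATA_L	akg_c + ala__L_c <-> glu__L_c + pyr_c	-1000	1000	alaT	2.6.1.2	amino acids
ASPTA	akg_c + asp__L_c <-> glu__L_c + oaa_c	-1000	1000	aspC	2.6.1.1	amino acids
CO2t	co2_e <-> co2_c	-1000	1000			transport
H2Ot	h2o_e <-> h2o_c	-1000	1000			transport
NH4t	nh4_e -> nh4_c	0	1000	amtB		transport
PIt	pi_e + h_e -> pi_c + h_c	0	1000	pitA		transport
GLUt	glu__L_e + h_e -> glu__L_c + h_c	0	1000	gltP		transport
CYSt	cys__L_e + h_e -> cys__L_c + h_c	0	1000	tcyP		transport
METt	met__L_e + h_e -> met__L_c + h_c	0	1000	metT		transport
SUCCt	succ_c + 2 h_c -> succ_e + 2 h_e	0	1000	dcuB		transport
ACt	ac_c + h_c -> ac_e + h_e	0	1000			transport
FORt	for_c + h_c -> for_e + h_e	0	1000	focA		transport
ETOHt	etoh_c -> etoh_e	0	1000			transport
PROT_SYN	2.355062395023 glu__L_c + 2.826074874028 ala__L_c + 1.884049916018 asp__L_c + 0.942024958009 cys__L_c + 1.413037437014 met__L_c + 40.507073194397 atp_c + 31.086823614305 h2o_c -> 40.5070731944 adp_c + 40.5070731944 pi_c + 40.5070731944 h_c + protein_g	0	1000			biomass
GLYC_SYN	6.1674715217 g6p_c + 6.1674715217 atp_c -> glycogen_g + 6.1674715217 adp_c + 6.1674715217 ppi_c	0	1000			biomass
PPA	ppi_c + h2o_c -> 2 pi_c + h_c	0	1000	ppa	3.6.1.1	energy
BIOMASS	0.7 protein_g + 0.3 glycogen_g + 40.0 atp_c + 40.0 h2o_c -> 40 adp_c + 40 pi_c + 40 h_c	0	1000			biomass
ATPM	atp_c + h2o_c -> adp_c + pi_c + h_c	0	1000			energy
EX_glc__D_e	glc__D_e -> 	-10	1000			exchange
EX_sbt__D_e	sbt__D_e -> 	0	1000			exchange
EX_xyl__D_e	xyl__D_e -> 	0	1000			exchange
EX_succ_e	succ_e -> 	0	1000			exchange
EX_ac_e	ac_e -> 	0	1000			exchange
EX_for_e	for_e -> 	0	1000			exchange
EX_etoh_e	etoh_e -> 	0	1000			exchange
EX_co2_e	co2_e -> 	-1000	1000			exchange
EX_h_e	h_e -> 	-1000	1000			exchange
EX_h2o_e	h2o_e -> 	-1000	1000			exchange
EX_pi_e	pi_e -> 	-1000	1000			exchange
EX_nh4_e	nh4_e -> 	-1000	1000			exchange
EX_glu__L_e	glu__L_e -> 	-0.5	1000			exchange
EX_cys__L_e	cys__L_e -> 	-1000	1000			exchange
EX_met__L_e	met__L_e -> 	-1000	1000			exchange
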