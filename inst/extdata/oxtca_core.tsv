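#! name: OXTCA-CORE
#! version: oxidative template
#! objective: EX_succ_e
rxn_id	equation	lb	ub	genes	ec	subsystem
GLCt2	glc__D_e + h_e -> glc__D_c + h_c	0	1000			transport
HEX1	glc__D_c + atp_c -> g6p_c + adp_c + h_c	0	1000		2.7.1.2	glycolysis
PGI	g6p_c <-> f6p_c	-1000	1000		5.3.1.9	glycolysis
PFK	f6p_c + atp_c -> fdp_c + adp_c + h_c	0	1000		2.7.1.11	glycolysis
FBA	fdp_c <-> dhap_c + g3p_c	-1000	1000		4.1.2.13	glycolysis
TPI	dhap_c <-> g3p_c	-1000	1000		5.3.1.1	glycolysis
GAPD	g3p_c + nad_c + pi_c <-> 13dpg_c + nadh_c + h_c	-1000	1000		1.2.1.12	glycolysis
PGK	13dpg_c + adp_c <-> 3pg_c + atp_c	-1000	1000		2.7.2.3	glycolysis
PGM	3pg_c <-> 2pg_c	-1000	1000		5.4.2.12	glycolysis
ENO	2pg_c <-> pep_c + h2o_c	-1000	1000		4.2.1.11	glycolysis
PYK	pep_c + adp_c + h_c -> pyr_c + atp_c	0	1000		2.7.1.40	glycolysis
PDH	pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c	0	1000		1.2.4.1	TCA
CS	accoa_c + oaa_c + h2o_c -> cit_c + coa_c + h_c	0	1000		2.3.3.1	TCA
ACONT	cit_c <-> icit_c	-1000	1000		4.2.1.3	TCA
ICDHx	icit_c + nad_c -> akg_c + co2_c + nadh_c	0	1000		1.1.1.41	TCA
AKGD	akg_c + coa_c + nad_c -> succoa_c + co2_c + nadh_c	0	1000		1.2.4.2	TCA
SUCOAS	succoa_c + adp_c + pi_c <-> succ_c + atp_c + coa_c	-1000	1000		6.2.1.5	TCA
PPC	pep_c + co2_c + h2o_c -> oaa_c + pi_c + h_c	0	1000		4.1.1.31	anaplerosis
NOX	nadh_c + h_c + 0.5 o2_c -> nad_c + h2o_c	0	1000			respiration
PTAr	accoa_c + pi_c <-> actp_c + coa_c	-1000	1000		2.3.1.8	overflow
ACKr	actp_c + adp_c <-> ac_c + atp_c	-1000	1000		2.7.2.1	overflow
ACt	ac_c + h_c -> ac_e + h_e	0	1000			transport
ATPM	atp_c + h2o_c -> adp_c + pi_c + h_c	0	1000			energy
O2t	o2_e <-> o2_c	-1000	1000			transport
CO2t	co2_e <-> co2_c	-1000	1000			transport
H2Ot	h2o_e <-> h2o_c	-1000	1000			transport
Ht	h_e <-> h_c	-1000	1000			transport
PIt	pi_e + h_e -> pi_c + h_c	0	1000			transport
SUCCt	succ_c -> succ_e	0	1000			transport
EX_glc__D_e	glc__D_e -> 	-10	1000			exchange
EX_succ_e	succ_e -> 	0	1000			exchange
EX_ac_e	ac_e -> 	0	1000			exchange
EX_co2_e	co2_e -> 	-1000	1000			exchange
EX_o2_e	o2_e -> 	-1000	1000			exchange
EX_h_e	h_e -> 	-1000	1000			exchange
EX_h2o_e	h2o_e -> 	-1000	1000			exchange
EX_pi_e	pi_e -> 	-1000	1000			exchange
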