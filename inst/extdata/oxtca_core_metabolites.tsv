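id	name	formula	charge	compartment
glc__D_e	D-glucose	C6H12O6	0	e
succ_e	succinate	C4H4O4	-2	e
ac_e	acetate	C2H3O2	-1	e
co2_e	carbon dioxide	CO2	0	e
h_e	proton	H	1	e
h2o_e	water	H2O	0	e
pi_e	phosphate	HO4P	-2	e
o2_e	oxygen	O2	0	e
glc__D_c	D-glucose	C6H12O6	0	c
g6p_c	glucose 6-phosphate	C6H11O9P	-2	c
f6p_c	fructose 6-phosphate	C6H11O9P	-2	c
fdp_c	fructose 1,6-bisphosphate	C6H10O12P2	-4	c
dhap_c	dihydroxyacetone phosphate	C3H5O6P	-2	c
g3p_c	glyceraldehyde 3-phosphate	C3H5O6P	-2	c
13dpg_c	1,3-bisphosphoglycerate	C3H4O10P2	-4	c
3pg_c	3-phosphoglycerate	C3H4O7P	-3	c
2pg_c	2-phosphoglycerate	C3H4O7P	-3	c
pep_c	phosphoenolpyruvate	C3H2O6P	-3	c
pyr_c	pyruvate	C3H3O3	-1	c
oaa_c	oxaloacetate	C4H2O5	-2	c
succ_c	succinate	C4H4O4	-2	c
cit_c	citrate	C6H5O7	-3	c
icit_c	isocitrate	C6H5O7	-3	c
akg_c	2-oxoglutarate	C5H4O5	-2	c
succoa_c	succinyl-CoA	C25H35N7O19P3S	-5	c
accoa_c	acetyl-CoA	C23H34N7O17P3S	-4	c
coa_c	coenzyme A	C21H32N7O16P3S	-4	c
actp_c	acetyl phosphate	C2H3O5P	-2	c
ac_c	acetate	C2H3O2	-1	c
co2_c	carbon dioxide	CO2	0	c
h_c	proton	H	1	c
h2o_c	water	H2O	0	c
pi_c	phosphate	HO4P	-2	c
atp_c	ATP	C10H12N5O13P3	-4	c
adp_c	ADP	C10H12N5O10P2	-3	c
nad_c	NAD+	C21H26N7O14P2	-1	c
nadh_c	NADH	C21H27N7O14P2	-2	c
o2_c	oxygen	O2	0	c
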