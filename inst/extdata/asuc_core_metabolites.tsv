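id	name	formula	charge	compartment
glc__D_e	D-glucose	C6H12O6	0	e
sbt__D_e	D-sorbitol	C6H14O6	0	e
xyl__D_e	D-xylose	C5H10O5	0	e
succ_e	succinate	C4H4O4	-2	e
ac_e	acetate	C2H3O2	-1	e
for_e	formate	CHO2	-1	e
etoh_e	ethanol	C2H6O	0	e
co2_e	carbon dioxide	CO2	0	e
h_e	proton	H	1	e
h2o_e	water	H2O	0	e
pi_e	phosphate	HO4P	-2	e
nh4_e	ammonium	H4N	1	e
glu__L_e	L-glutamate	C5H8NO4	-1	e
cys__L_e	L-cysteine	C3H7NO2S	0	e
met__L_e	L-methionine	C5H11NO2S	0	e
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
ru5p__D_c	ribulose 5-phosphate	C5H9O8P	-2	c
x5p__D_c	xylulose 5-phosphate	C5H9O8P	-2	c
xyl__D_c	D-xylose	C5H10O5	0	c
xylu__D_c	D-xylulose	C5H10O5	0	c
sbt6p_c	sorbitol 6-phosphate	C6H13O9P	-2	c
oaa_c	oxaloacetate	C4H2O5	-2	c
mal__L_c	L-malate	C4H4O5	-2	c
fum_c	fumarate	C4H2O4	-2	c
succ_c	succinate	C4H4O4	-2	c
akg_c	2-oxoglutarate	C5H4O5	-2	c
accoa_c	acetyl-CoA	C23H34N7O17P3S	-4	c
coa_c	coenzyme A	C21H32N7O16P3S	-4	c
actp_c	acetyl phosphate	C2H3O5P	-2	c
ac_c	acetate	C2H3O2	-1	c
for_c	formate	CHO2	-1	c
acald_c	acetaldehyde	C2H4O	0	c
etoh_c	ethanol	C2H6O	0	c
co2_c	carbon dioxide	CO2	0	c
h_c	proton	H	1	c
h2o_c	water	H2O	0	c
pi_c	phosphate	HO4P	-2	c
ppi_c	diphosphate	HO7P2	-3	c
nh4_c	ammonium	H4N	1	c
atp_c	ATP	C10H12N5O13P3	-4	c
adp_c	ADP	C10H12N5O10P2	-3	c
nad_c	NAD+	C21H26N7O14P2	-1	c
nadh_c	NADH	C21H27N7O14P2	-2	c
nadp_c	NADP+	C21H25N7O17P3	-3	c
nadph_c	NADPH	C21H26N7O17P3	-4	c
mqn8_c	menaquinone	C11H8O2	0	c
mql8_c	menaquinol	C11H10O2	0	c
glu__L_c	L-glutamate	C5H8NO4	-1	c
ala__L_c	L-alanine	C3H7NO2	0	c
asp__L_c	L-aspartate	C4H6NO4	-1	c
cys__L_c	L-cysteine	C3H7NO2S	0	c
met__L_c	L-methionine	C5H11NO2S	0	c
protein_g	protein (1 g)		0	c
glycogen_g	glycogen (1 g)		0	c
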