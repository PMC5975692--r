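query	subject	score	ec	lineage
cds0001	sbj0001	200	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_1
cds0001	sbj0002	186	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0003	172.98	2.7.1.11	Bacteria;Pseudomonadota;alt_1_3;alt_2_3;alt_3_3;alt_4_3;alt_5_3
cds0001	sbj0004	160.8714	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0005	149.610402	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0006	139.13767386	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0007	129.3980366898	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0008	120.340174121514	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0009	111.916361933008	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_9
cds0001	sbj0010	104.082216597698	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0011	96.7964614358587	3.6.1.1	Bacteria;Pseudomonadota;alt_1_11;alt_2_11;alt_3_11;alt_4_11;alt_5_11
cds0001	sbj0012	90.0207091353486	2.6.1.1	Bacteria;Pseudomonadota;alt_1_12;alt_2_12;alt_3_12;alt_4_12;alt_5_12
cds0001	sbj0013	83.7192594958742	2.7.1.11	Bacteria;Pseudomonadota;alt_1_13;alt_2_13;alt_3_13;alt_4_13;alt_5_13
cds0001	sbj0014	77.858911331163	2.6.1.1	Bacteria;alt_1_14;alt_2_14;alt_3_14;alt_4_14;alt_5_14;alt_6_14
cds0001	sbj0015	72.4087875379816	4.1.1.49	Bacteria;alt_1_15;alt_2_15;alt_3_15;alt_4_15;alt_5_15;alt_6_15
cds0001	sbj0016	67.3401724103229	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_16
cds0001	sbj0017	62.6263603416003	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;Actinobacillus succinogenes
cds0001	sbj0018	58.2425151176883	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_18
cds0001	sbj0019	54.1655390594501	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_19
cds0001	sbj0020	50.3739513252886	1.1.1.37	Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Actinobacillus;alt_1_20
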