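# Seeded fixture generators: a reduced Actinobacillus succinogenes
# central-carbon model (ASUC-CORE), an oxidative-TCA template (OXTCA-CORE),
# random toy networks with closed-form optima, and planted-truth homology
# tables. All generators are deterministic for fixed options/seed.

# -- metabolite catalog ------------------------------------------------------
# Charged species, BiGG-style ids. Formulas chosen so every enzymatic
# reaction below balances for mass and charge.
core_metabolite_catalog <- function() {
  def <- list(
    # extracellular
    c("glc__D_e", "D-glucose", "C6H12O6", 0, "e"),
    c("sbt__D_e", "D-sorbitol", "C6H14O6", 0, "e"),
    c("xyl__D_e", "D-xylose", "C5H10O5", 0, "e"),
    c("succ_e", "succinate", "C4H4O4", -2, "e"),
    c("ac_e", "acetate", "C2H3O2", -1, "e"),
    c("for_e", "formate", "CHO2", -1, "e"),
    c("etoh_e", "ethanol", "C2H6O", 0, "e"),
    c("co2_e", "carbon dioxide", "CO2", 0, "e"),
    c("h2_e", "dihydrogen", "H2", 0, "e"),
    c("h_e", "proton", "H", 1, "e"),
    c("h2o_e", "water", "H2O", 0, "e"),
    c("pi_e", "phosphate", "HO4P", -2, "e"),
    c("nh4_e", "ammonium", "H4N", 1, "e"),
    c("glu__L_e", "L-glutamate", "C5H8NO4", -1, "e"),
    c("cys__L_e", "L-cysteine", "C3H7NO2S", 0, "e"),
    c("met__L_e", "L-methionine", "C5H11NO2S", 0, "e"),
    c("glyc_e", "glycerol", "C3H8O3", 0, "e"),
    c("dmso_e", "dimethyl sulfoxide", "C2H6OS", 0, "e"),
    c("dms_e", "dimethyl sulfide", "C2H6S", 0, "e"),
    c("o2_e", "oxygen", "O2", 0, "e"),
    # cytosol
    c("glc__D_c", "D-glucose", "C6H12O6", 0, "c"),
    c("g6p_c", "glucose 6-phosphate", "C6H11O9P", -2, "c"),
    c("f6p_c", "fructose 6-phosphate", "C6H11O9P", -2, "c"),
    c("fdp_c", "fructose 1,6-bisphosphate", "C6H10O12P2", -4, "c"),
    c("dhap_c", "dihydroxyacetone phosphate", "C3H5O6P", -2, "c"),
    c("g3p_c", "glyceraldehyde 3-phosphate", "C3H5O6P", -2, "c"),
    c("13dpg_c", "1,3-bisphosphoglycerate", "C3H4O10P2", -4, "c"),
    c("3pg_c", "3-phosphoglycerate", "C3H4O7P", -3, "c"),
    c("2pg_c", "2-phosphoglycerate", "C3H4O7P", -3, "c"),
    c("pep_c", "phosphoenolpyruvate", "C3H2O6P", -3, "c"),
    c("pyr_c", "pyruvate", "C3H3O3", -1, "c"),
    c("ru5p__D_c", "ribulose 5-phosphate", "C5H9O8P", -2, "c"),
    c("x5p__D_c", "xylulose 5-phosphate", "C5H9O8P", -2, "c"),
    c("xyl__D_c", "D-xylose", "C5H10O5", 0, "c"),
    c("xylu__D_c", "D-xylulose", "C5H10O5", 0, "c"),
    c("sbt6p_c", "sorbitol 6-phosphate", "C6H13O9P", -2, "c"),
    c("oaa_c", "oxaloacetate", "C4H2O5", -2, "c"),
    c("mal__L_c", "L-malate", "C4H4O5", -2, "c"),
    c("fum_c", "fumarate", "C4H2O4", -2, "c"),
    c("succ_c", "succinate", "C4H4O4", -2, "c"),
    c("cit_c", "citrate", "C6H5O7", -3, "c"),
    c("icit_c", "isocitrate", "C6H5O7", -3, "c"),
    c("akg_c", "2-oxoglutarate", "C5H4O5", -2, "c"),
    c("succoa_c", "succinyl-CoA", "C25H35N7O19P3S", -5, "c"),
    c("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", -4, "c"),
    c("coa_c", "coenzyme A", "C21H32N7O16P3S", -4, "c"),
    c("actp_c", "acetyl phosphate", "C2H3O5P", -2, "c"),
    c("ac_c", "acetate", "C2H3O2", -1, "c"),
    c("for_c", "formate", "CHO2", -1, "c"),
    c("acald_c", "acetaldehyde", "C2H4O", 0, "c"),
    c("etoh_c", "ethanol", "C2H6O", 0, "c"),
    c("co2_c", "carbon dioxide", "CO2", 0, "c"),
    c("hco3_c", "bicarbonate", "CHO3", -1, "c"),
    c("h2_c", "dihydrogen", "H2", 0, "c"),
    c("h_c", "proton", "H", 1, "c"),
    c("h2o_c", "water", "H2O", 0, "c"),
    c("pi_c", "phosphate", "HO4P", -2, "c"),
    c("ppi_c", "diphosphate", "HO7P2", -3, "c"),
    c("nh4_c", "ammonium", "H4N", 1, "c"),
    c("atp_c", "ATP", "C10H12N5O13P3", -4, "c"),
    c("adp_c", "ADP", "C10H12N5O10P2", -3, "c"),
    c("nad_c", "NAD+", "C21H26N7O14P2", -1, "c"),
    c("nadh_c", "NADH", "C21H27N7O14P2", -2, "c"),
    c("nadp_c", "NADP+", "C21H25N7O17P3", -3, "c"),
    c("nadph_c", "NADPH", "C21H26N7O17P3", -4, "c"),
    c("mqn8_c", "menaquinone", "C11H8O2", 0, "c"),
    c("mql8_c", "menaquinol", "C11H10O2", 0, "c"),
    c("glu__L_c", "L-glutamate", "C5H8NO4", -1, "c"),
    c("ala__L_c", "L-alanine", "C3H7NO2", 0, "c"),
    c("asp__L_c", "L-aspartate", "C4H6NO4", -1, "c"),
    c("cys__L_c", "L-cysteine", "C3H7NO2S", 0, "c"),
    c("met__L_c", "L-methionine", "C5H11NO2S", 0, "c"),
    c("glyc_c", "glycerol", "C3H8O3", 0, "c"),
    c("glyc3p_c", "glycerol 3-phosphate", "C3H7O6P", -2, "c"),
    c("dmso_c", "dimethyl sulfoxide", "C2H6OS", 0, "c"),
    c("dms_c", "dimethyl sulfide", "C2H6S", 0, "c"),
    c("o2_c", "oxygen", "O2", 0, "c"),
    # biomass pseudo-species (1 g units, no formula)
    c("protein_g", "protein (1 g)", "", 0, "c"),
    c("glycogen_g", "glycogen (1 g)", "", 0, "c")
  )
  lapply(def, function(d) metabolite(d[[1]], name = d[[2]], formula = d[[3]],
                                     charge = as.numeric(d[[4]]),
                                     compartment = d[[5]]))
}

# shorthand: named stoichiometry vector
st <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), names(v))
}

rxn <- function(id, stoich, lb = 0, ub = UNBOUNDED_FLUX, gpr = "",
                ec = character(), subsystem = "", name = id) {
  reaction(id, stoich, lb = lb, ub = ub, gene_association = gpr,
           ec = ec, subsystem = subsystem, name = name)
}

rev_rxn <- function(id, stoich, gpr = "", ec = character(), subsystem = "",
                    name = id) {
  rxn(id, stoich, lb = -UNBOUNDED_FLUX, ub = UNBOUNDED_FLUX, gpr = gpr,
      ec = ec, subsystem = subsystem, name = name)
}

# Fixture amino-acid composition (molar fractions) used for the toy protein.
asuc_core_aa_frequencies <- function() {
  c(glu = 0.25, ala = 0.30, asp = 0.20, cys = 0.10, met = 0.15)
}

# Fixture macromolecular composition: only classes the reduced network can
# synthesize carry mass (protein + glycogen); full class set is supported by
# the builder and exercised in its own tests.
asuc_core_composition <- function(gam = 40, ngam = 0) {
  macro_composition(protein = 0.70, glycogen = 0.30, gam = gam, ngam = ngam)
}

asuc_core_macro_reactions <- function() {
  # charged-species masses (network formulas), so the audit closes exactly
  aa_formula_masses <- c(glu = molar_mass("C5H8NO4"),
                         ala = molar_mass("C3H7NO2"),
                         asp = molar_mass("C4H6NO4"),
                         cys = molar_mass("C3H7NO2S"),
                         met = molar_mass("C5H11NO2S"))
  prot <- protein_pseudoreaction(asuc_core_aa_frequencies(),
                                 aa_masses = aa_formula_masses)
  glyc_unit <- molar_mass("C6H10O5") / 1000      # anhydroglucose g/mmol
  k <- 1 / glyc_unit                             # mmol residue per g glycogen
  glyc <- rxn("GLYC_SYN",
              st(g6p_c = -k, atp_c = -k, glycogen_g = 1, adp_c = k, ppi_c = k),
              subsystem = "biomass", name = "glycogen synthesis (1 g)")
  list(protein = prot, glycogen = glyc)
}

#' Reduced A. succinogenes central-carbon fixture model (ASUC-CORE)
#'
#' An anaerobic, elementally balanced central-carbon network with the C3/C4
#' fermentation topology: glucose uptake by PEP:PTS and/or proton symport,
#' sorbitol PTS (extra NADH via sorbitol-6-phosphate dehydrogenase), xylose
#' entry into the non-oxidative pentose-phosphate pathway, glycolysis,
#' oxidative PPP, the PEP node (ATP-generating PEP carboxykinase and pyruvate
#' kinase), the reductive C4 branch (malate dehydrogenase, fumarase,
#' menaquinol-dependent fumarate reductase), NADP-malic enzyme bridging
#' C3/C4, oxaloacetate decarboxylase, the C3 branch (pyruvate-formate lyase,
#' menaquinone formate dehydrogenase, phosphotransacetylase/acetate kinase,
#' acetaldehyde/alcohol dehydrogenase), NADH dehydrogenase into the
#' menaquinone pool, a toy biomass built by the biomass module, and ATP
#' maintenance. Succinyl-CoA ligase is deliberately absent, so its zero-flux
#' constraint is structural. The default medium supplies glucose at
#' -10 mmol/gDCW/h, unconstrained CO2/H+/water/phosphate/ammonium,
#' unconstrained cysteine and methionine and a capped glutamate uptake.
#'
#' @param transporter glucose uptake mechanism: `"pts"`, `"symport"` or
#'   `"both"`.
#' @param me2 malic-enzyme direction: `"forward"` (decarboxylating only),
#'   `"reverse"` (carboxylating only) or `"reversible"`.
#' @param hydrogenase add a menaquinone-reducing hydrogenase plus H2
#'   transport/exchange.
#' @param dmso add DMSO reductase plus an ATP-dependent glycerol pathway
#'   (glycerol is otherwise absent from the network).
#' @param bicarbonate add a carbonic-anhydrase CO2/HCO3- interconversion
#'   (yield-neutral by construction).
#' @param gam,ngam growth- and non-growth-associated ATP maintenance.
#' @return a validated `cb_model` with the biomass reaction as objective.
#' @export
asuc_core_model <- function(transporter = c("both", "pts", "symport"),
                            me2 = c("reversible", "forward", "reverse"),
                            hydrogenase = FALSE, dmso = FALSE,
                            bicarbonate = FALSE, gam = 40, ngam = 0) {
  transporter <- match.arg(transporter)
  me2 <- match.arg(me2)
  U <- UNBOUNDED_FLUX
  r <- list()
  add <- function(x) r[[x$id]] <<- x

  ## glucose uptake
  if (transporter %in% c("pts", "both")) {
    add(rxn("GLCpts", st(glc__D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
            gpr = "(ptsG and ptsH and ptsI)", ec = "2.7.1.199",
            subsystem = "transport", name = "glucose PEP:PTS"))
  }
  if (transporter %in% c("symport", "both")) {
    add(rxn("GLCt2", st(glc__D_e = -1, h_e = -1, glc__D_c = 1, h_c = 1),
            gpr = "gluP", subsystem = "transport",
            name = "glucose proton symport"))
    add(rxn("HEX1", st(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
            gpr = "glk", ec = "2.7.1.2", subsystem = "glycolysis",
            name = "hexokinase"))
  }
  ## sorbitol and xylose
  add(rxn("SBTpts", st(sbt__D_e = -1, pep_c = -1, sbt6p_c = 1, pyr_c = 1),
          gpr = "(srlA and srlB and srlE)", ec = "2.7.1.198",
          subsystem = "transport", name = "sorbitol PEP:PTS"))
  add(rxn("S6PD", st(sbt6p_c = -1, nad_c = -1, f6p_c = 1, nadh_c = 1, h_c = 1),
          gpr = "srlD", ec = "1.1.1.140", subsystem = "alternate carbon",
          name = "sorbitol-6-phosphate dehydrogenase"))
  add(rxn("XYLt2", st(xyl__D_e = -1, h_e = -1, xyl__D_c = 1, h_c = 1),
          gpr = "xylT", subsystem = "transport", name = "xylose proton symport"))
  add(rev_rxn("XYLI", st(xyl__D_c = -1, xylu__D_c = 1),
              gpr = "xylA", ec = "5.3.1.5", subsystem = "alternate carbon",
              name = "xylose isomerase"))
  add(rxn("XYLK", st(xylu__D_c = -1, atp_c = -1, x5p__D_c = 1, adp_c = 1, h_c = 1),
          gpr = "xylB", ec = "2.7.1.17", subsystem = "alternate carbon",
          name = "xylulokinase"))
  ## glycolysis
  add(rev_rxn("PGI", st(g6p_c = -1, f6p_c = 1), gpr = "pgi", ec = "5.3.1.9",
              subsystem = "glycolysis", name = "glucose-6-phosphate isomerase"))
  add(rxn("PFK", st(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1),
          gpr = "pfkA", ec = "2.7.1.11", subsystem = "glycolysis",
          name = "phosphofructokinase"))
  add(rev_rxn("FBA", st(fdp_c = -1, dhap_c = 1, g3p_c = 1), gpr = "fba",
              ec = "4.1.2.13", subsystem = "glycolysis",
              name = "fructose-bisphosphate aldolase"))
  add(rxn("FBP", st(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1),
          gpr = "fbp", ec = "3.1.3.11", subsystem = "glycolysis",
          name = "fructose-1,6-bisphosphatase"))
  add(rev_rxn("TPI", st(dhap_c = -1, g3p_c = 1), gpr = "tpiA", ec = "5.3.1.1",
              subsystem = "glycolysis", name = "triose-phosphate isomerase"))
  add(rev_rxn("GAPD", st(g3p_c = -1, nad_c = -1, pi_c = -1,
                         `13dpg_c` = 1, nadh_c = 1, h_c = 1),
              gpr = "gapA", ec = "1.2.1.12", subsystem = "glycolysis",
              name = "glyceraldehyde-3-phosphate dehydrogenase"))
  add(rev_rxn("PGK", st(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1),
              gpr = "pgk", ec = "2.7.2.3", subsystem = "glycolysis",
              name = "phosphoglycerate kinase"))
  add(rev_rxn("PGM", st(`3pg_c` = -1, `2pg_c` = 1), gpr = "gpmA",
              ec = "5.4.2.12", subsystem = "glycolysis",
              name = "phosphoglycerate mutase"))
  add(rev_rxn("ENO", st(`2pg_c` = -1, pep_c = 1, h2o_c = 1), gpr = "eno",
              ec = "4.2.1.11", subsystem = "glycolysis", name = "enolase"))
  add(rxn("PYK", st(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
          gpr = "pykA", ec = "2.7.1.40", subsystem = "glycolysis",
          name = "pyruvate kinase"))
  ## pentose phosphate pathway (oxidative lump + non-oxidative lump)
  add(rxn("GND", st(g6p_c = -1, nadp_c = -2, h2o_c = -1,
                    ru5p__D_c = 1, co2_c = 1, nadph_c = 2, h_c = 2),
          gpr = "(zwf and pgl and gnd)", ec = c("1.1.1.49", "1.1.1.44"),
          subsystem = "pentose phosphate",
          name = "oxidative PPP (lumped to ribulose 5-phosphate)"))
  add(rev_rxn("RPE", st(ru5p__D_c = -1, x5p__D_c = 1), gpr = "rpe",
              ec = "5.1.3.1", subsystem = "pentose phosphate",
              name = "ribulose-5-phosphate epimerase"))
  add(rev_rxn("TKTL", st(ru5p__D_c = -3, f6p_c = 2, g3p_c = 1),
              gpr = "(tktA and talB)", ec = c("2.2.1.1", "2.2.1.2"),
              subsystem = "pentose phosphate",
              name = "non-oxidative PPP (lumped)"))
  ## PEP node and C4 branch
  add(rxn("PPCK", st(pep_c = -1, co2_c = -1, adp_c = -1, oaa_c = 1, atp_c = 1),
          gpr = "pckA", ec = "4.1.1.49", subsystem = "C4 branch",
          name = "PEP carboxykinase (carboxylating)"))
  add(rev_rxn("MDH", st(oaa_c = -1, nadh_c = -1, h_c = -1,
                        mal__L_c = 1, nad_c = 1),
              gpr = "mdh", ec = "1.1.1.37", subsystem = "C4 branch",
              name = "malate dehydrogenase"))
  add(rev_rxn("FUM", st(fum_c = -1, h2o_c = -1, mal__L_c = 1),
              gpr = "(fumA or fumC)", ec = "4.2.1.2", subsystem = "C4 branch",
              name = "fumarase"))
  add(rxn("FRDmq", st(fum_c = -1, mql8_c = -1, succ_c = 1, mqn8_c = 1),
          gpr = "(frdA and frdB and frdC and frdD)", ec = "1.3.5.4",
          subsystem = "C4 branch",
          name = "fumarate reductase (menaquinol)"))
  me2_bounds <- switch(me2,
                       forward = c(0, U),
                       reverse = c(-U, 0),
                       reversible = c(-U, U))
  add(rxn("ME2", st(mal__L_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1,
                    nadph_c = 1),
          lb = me2_bounds[1], ub = me2_bounds[2],
          gpr = "maeB", ec = "1.1.1.40", subsystem = "C3-C4 bridge",
          name = "NADP-malic enzyme"))
  add(rxn("OAADC", st(oaa_c = -1, h_c = -1, pyr_c = 1, co2_c = 1),
          gpr = "oadA", ec = "4.1.1.3", subsystem = "C3-C4 bridge",
          name = "oxaloacetate decarboxylase"))
  ## C3 branch
  add(rxn("PFL", st(pyr_c = -1, coa_c = -1, accoa_c = 1, for_c = 1),
          gpr = "pflB", ec = "2.3.1.54", subsystem = "C3 branch",
          name = "pyruvate-formate lyase"))
  add(rxn("FDHmq", st(for_c = -1, h_c = -3, mqn8_c = -1,
                      co2_c = 1, mql8_c = 1, h_e = 2),
          gpr = "(fdhA and fdhB)", ec = "1.17.5.3", subsystem = "C3 branch",
          name = "formate dehydrogenase (menaquinone, electrogenic)"))
  add(rev_rxn("PTAr", st(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1),
              gpr = "pta", ec = "2.3.1.8", subsystem = "C3 branch",
              name = "phosphotransacetylase"))
  add(rev_rxn("ACKr", st(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
              gpr = "ackA", ec = "2.7.2.1", subsystem = "C3 branch",
              name = "acetate kinase"))
  add(rev_rxn("ACALD", st(accoa_c = -1, nadh_c = -1, h_c = -1,
                          acald_c = 1, coa_c = 1, nad_c = 1),
              gpr = "adhE", ec = "1.2.1.10", subsystem = "C3 branch",
              name = "acetaldehyde dehydrogenase"))
  add(rev_rxn("ALCD2x", st(acald_c = -1, nadh_c = -1, h_c = -1,
                           etoh_c = 1, nad_c = 1),
              gpr = "adhE", ec = "1.1.1.1", subsystem = "C3 branch",
              name = "alcohol dehydrogenase"))
  ## respiratory chain pieces
  add(rxn("NADHDH", st(nadh_c = -1, h_c = -3, mqn8_c = -1,
                       nad_c = 1, mql8_c = 1, h_e = 2),
          gpr = "(nuoA and nuoB)", ec = "1.6.5.3", subsystem = "respiration",
          name = "NADH dehydrogenase (menaquinone, electrogenic)"))
  add(rev_rxn("ATPS4r", st(adp_c = -1, pi_c = -1, h_e = -4,
                           atp_c = 1, h2o_c = 1, h_c = 3),
              gpr = "(atpA and atpB and atpC)", ec = "7.1.2.2",
              subsystem = "respiration", name = "ATP synthase (4 H+)"))
  if (hydrogenase) {
    add(rxn("HYD", st(h2_c = -1, mqn8_c = -1, h_c = -2, mql8_c = 1, h_e = 2),
            gpr = "(hyaA and hyaB)", ec = "1.12.5.1",
            subsystem = "respiration",
            name = "hydrogenase (menaquinone, electrogenic)"))
    add(rev_rxn("H2t", st(h2_e = -1, h2_c = 1), subsystem = "transport",
                name = "hydrogen diffusion"))
  }
  if (bicarbonate) {
    add(rev_rxn("HCO3E", st(co2_c = -1, h2o_c = -1, hco3_c = 1, h_c = 1),
                gpr = "can", ec = "4.2.1.1", subsystem = "C3-C4 bridge",
                name = "carbonic anhydrase"))
  }
  if (dmso) {
    add(rxn("GLYCabc", st(glyc_e = -1, atp_c = -1, h2o_c = -1,
                          glyc_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
            gpr = "(glpV and glpS)", subsystem = "transport",
            name = "glycerol ABC transport"))
    add(rxn("GLYK", st(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1,
                       h_c = 1),
            gpr = "glpK", ec = "2.7.1.30", subsystem = "alternate carbon",
            name = "glycerol kinase"))
    add(rxn("G3PD1", st(glyc3p_c = -1, mqn8_c = -1, dhap_c = 1, mql8_c = 1),
            gpr = "glpD", ec = "1.1.5.3", subsystem = "alternate carbon",
            name = "glycerol-3-phosphate dehydrogenase (menaquinone)"))
    add(rxn("DMSOt", st(dmso_e = -1, dmso_c = 1), subsystem = "transport",
            name = "DMSO uptake"))
    add(rxn("DMSt", st(dms_c = -1, dms_e = 1), subsystem = "transport",
            name = "DMS efflux"))
    add(rxn("DMSOR", st(dmso_c = -1, mql8_c = -1, dms_c = 1, mqn8_c = 1,
                        h2o_c = 1),
            gpr = "(dmsA and dmsB)", ec = "1.8.5.3", subsystem = "respiration",
            name = "DMSO reductase (menaquinol)"))
  }
  ## amino-acid and nitrogen metabolism
  add(rev_rxn("GLUDy", st(glu__L_c = -1, h2o_c = -1, nadp_c = -1,
                          akg_c = 1, nh4_c = 1, nadph_c = 1, h_c = 1),
              gpr = "gdhA", ec = "1.4.1.4", subsystem = "amino acids",
              name = "glutamate dehydrogenase (NADP)"))
  add(rev_rxn("ALATA_L", st(akg_c = -1, ala__L_c = -1, glu__L_c = 1, pyr_c = 1),
              gpr = "alaT", ec = "2.6.1.2", subsystem = "amino acids",
              name = "alanine transaminase"))
  add(rev_rxn("ASPTA", st(akg_c = -1, asp__L_c = -1, glu__L_c = 1, oaa_c = 1),
              gpr = "aspC", ec = "2.6.1.1", subsystem = "amino acids",
              name = "aspartate transaminase"))
  ## transport and exchange
  add(rev_rxn("CO2t", st(co2_e = -1, co2_c = 1), subsystem = "transport",
              name = "CO2 diffusion"))
  add(rev_rxn("H2Ot", st(h2o_e = -1, h2o_c = 1), subsystem = "transport",
              name = "water diffusion"))
  add(rxn("NH4t", st(nh4_e = -1, nh4_c = 1), subsystem = "transport",
          gpr = "amtB", name = "ammonium transport"))
  add(rxn("PIt", st(pi_e = -1, h_e = -1, pi_c = 1, h_c = 1),
          gpr = "pitA", subsystem = "transport", name = "phosphate symport"))
  add(rxn("GLUt", st(glu__L_e = -1, h_e = -1, glu__L_c = 1, h_c = 1),
          gpr = "gltP", subsystem = "transport", name = "glutamate symport"))
  add(rxn("CYSt", st(cys__L_e = -1, h_e = -1, cys__L_c = 1, h_c = 1),
          gpr = "tcyP", subsystem = "transport", name = "cysteine symport"))
  add(rxn("METt", st(met__L_e = -1, h_e = -1, met__L_c = 1, h_c = 1),
          gpr = "metT", subsystem = "transport", name = "methionine symport"))
  add(rxn("SUCCt", st(succ_c = -1, h_c = -2, succ_e = 1, h_e = 2),
          subsystem = "transport", gpr = "dcuB",
          name = "succinate efflux (electroneutral)"))
  add(rxn("ACt", st(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1),
          subsystem = "transport", name = "acetate efflux (electroneutral)"))
  add(rxn("FORt", st(for_c = -1, h_c = -1, for_e = 1, h_e = 1),
          subsystem = "transport", gpr = "focA",
          name = "formate efflux (electroneutral)"))
  add(rxn("ETOHt", st(etoh_c = -1, etoh_e = 1), subsystem = "transport",
          name = "ethanol efflux"))
  ## biomass machinery
  macro <- asuc_core_macro_reactions()
  add(macro$protein)
  add(macro$glycogen)
  add(rxn("PPA", st(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1),
          gpr = "ppa", ec = "3.6.1.1", subsystem = "energy",
          name = "inorganic pyrophosphatase"))
  comp <- asuc_core_composition(gam = gam, ngam = ngam)
  add(assemble_biomass(comp, macro))
  add(rxn("ATPM", st(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
          lb = ngam, ub = U, subsystem = "energy",
          name = "ATP maintenance"))
  ## exchanges with the default anaerobic glucose medium
  ex <- function(met, lb, ub = U) {
    id <- paste0("EX_", met)
    r[[id]] <<- rxn(id, stats::setNames(-1, met), lb = lb, ub = ub,
                    subsystem = "exchange", name = paste("exchange of", met))
  }
  ex("glc__D_e", -10); ex("sbt__D_e", 0); ex("xyl__D_e", 0)
  ex("succ_e", 0); ex("ac_e", 0); ex("for_e", 0); ex("etoh_e", 0)
  ex("co2_e", -U); ex("h_e", -U); ex("h2o_e", -U); ex("pi_e", -U)
  ex("nh4_e", -U); ex("glu__L_e", -0.5); ex("cys__L_e", -U); ex("met__L_e", -U)
  if (hydrogenase) ex("h2_e", 0)
  if (dmso) { ex("glyc_e", 0); ex("dmso_e", 0); ex("dms_e", 0) }

  used <- unique(unlist(lapply(r, function(x) names(x$stoich))))
  mets <- Filter(function(m) m$id %in% used, core_metabolite_catalog())
  build_model(mets, unname(r), objective_id = "BIOMASS",
              name = "ASUC-CORE",
              version = paste(transporter, me2,
                              if (hydrogenase) "hyd" else "",
                              if (dmso) "dmso" else ""))
}

#' Oxidative-TCA template fixture model (OXTCA-CORE)
#'
#' Aerobic template for the oxidative succinate route: glycolysis, pyruvate
#' dehydrogenase, citrate synthase through succinyl-CoA synthetase ending at
#' succinate export, PEP carboxylase anaplerosis and an oxygen-dependent NADH
#' sink. No fumarate reductase and no PEP carboxykinase, so succinate can
#' only arise oxidatively. Objective: succinate exchange.
#'
#' @return a validated `cb_model`.
#' @export
oxtca_core_model <- function() {
  U <- UNBOUNDED_FLUX
  r <- list()
  add <- function(x) r[[x$id]] <<- x
  add(rxn("GLCt2", st(glc__D_e = -1, h_e = -1, glc__D_c = 1, h_c = 1),
          subsystem = "transport", name = "glucose proton symport"))
  add(rxn("HEX1", st(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
          ec = "2.7.1.2", subsystem = "glycolysis", name = "hexokinase"))
  add(rev_rxn("PGI", st(g6p_c = -1, f6p_c = 1), ec = "5.3.1.9",
              subsystem = "glycolysis"))
  add(rxn("PFK", st(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1),
          ec = "2.7.1.11", subsystem = "glycolysis"))
  add(rev_rxn("FBA", st(fdp_c = -1, dhap_c = 1, g3p_c = 1), ec = "4.1.2.13",
              subsystem = "glycolysis"))
  add(rev_rxn("TPI", st(dhap_c = -1, g3p_c = 1), ec = "5.3.1.1",
              subsystem = "glycolysis"))
  add(rev_rxn("GAPD", st(g3p_c = -1, nad_c = -1, pi_c = -1,
                         `13dpg_c` = 1, nadh_c = 1, h_c = 1),
              ec = "1.2.1.12", subsystem = "glycolysis"))
  add(rev_rxn("PGK", st(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1),
              ec = "2.7.2.3", subsystem = "glycolysis"))
  add(rev_rxn("PGM", st(`3pg_c` = -1, `2pg_c` = 1), ec = "5.4.2.12",
              subsystem = "glycolysis"))
  add(rev_rxn("ENO", st(`2pg_c` = -1, pep_c = 1, h2o_c = 1), ec = "4.2.1.11",
              subsystem = "glycolysis"))
  add(rxn("PYK", st(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
          ec = "2.7.1.40", subsystem = "glycolysis"))
  add(rxn("PDH", st(pyr_c = -1, coa_c = -1, nad_c = -1,
                    accoa_c = 1, co2_c = 1, nadh_c = 1),
          ec = "1.2.4.1", subsystem = "TCA", name = "pyruvate dehydrogenase"))
  add(rxn("CS", st(accoa_c = -1, oaa_c = -1, h2o_c = -1,
                   cit_c = 1, coa_c = 1, h_c = 1),
          ec = "2.3.3.1", subsystem = "TCA", name = "citrate synthase"))
  add(rev_rxn("ACONT", st(cit_c = -1, icit_c = 1), ec = "4.2.1.3",
              subsystem = "TCA", name = "aconitase"))
  add(rxn("ICDHx", st(icit_c = -1, nad_c = -1, akg_c = 1, co2_c = 1,
                      nadh_c = 1),
          ec = "1.1.1.41", subsystem = "TCA",
          name = "isocitrate dehydrogenase"))
  add(rxn("AKGD", st(akg_c = -1, coa_c = -1, nad_c = -1,
                     succoa_c = 1, co2_c = 1, nadh_c = 1),
          ec = "1.2.4.2", subsystem = "TCA",
          name = "2-oxoglutarate dehydrogenase"))
  add(rev_rxn("SUCOAS", st(succoa_c = -1, adp_c = -1, pi_c = -1,
                           succ_c = 1, atp_c = 1, coa_c = 1),
              ec = "6.2.1.5", subsystem = "TCA",
              name = "succinyl-CoA synthetase"))
  add(rxn("PPC", st(pep_c = -1, co2_c = -1, h2o_c = -1,
                    oaa_c = 1, pi_c = 1, h_c = 1),
          ec = "4.1.1.31", subsystem = "anaplerosis",
          name = "PEP carboxylase"))
  add(rxn("NOX", st(nadh_c = -1, h_c = -1, o2_c = -0.5, nad_c = 1, h2o_c = 1),
          subsystem = "respiration", name = "NADH oxidase (O2 sink)"))
  add(rev_rxn("PTAr", st(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1),
              ec = "2.3.1.8", subsystem = "overflow"))
  add(rev_rxn("ACKr", st(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
              ec = "2.7.2.1", subsystem = "overflow"))
  add(rxn("ACt", st(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1),
          subsystem = "transport", name = "acetate efflux (electroneutral)"))
  add(rxn("ATPM", st(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
          lb = 0, ub = U, subsystem = "energy", name = "ATP maintenance"))
  add(rev_rxn("O2t", st(o2_e = -1, o2_c = 1), subsystem = "transport"))
  add(rev_rxn("CO2t", st(co2_e = -1, co2_c = 1), subsystem = "transport"))
  add(rev_rxn("H2Ot", st(h2o_e = -1, h2o_c = 1), subsystem = "transport"))
  add(rev_rxn("Ht", st(h_e = -1, h_c = 1), subsystem = "transport"))
  add(rxn("PIt", st(pi_e = -1, h_e = -1, pi_c = 1, h_c = 1),
          subsystem = "transport"))
  add(rxn("SUCCt", st(succ_c = -1, succ_e = 1), subsystem = "transport"))
  ex <- function(met, lb, ub = U) {
    id <- paste0("EX_", met)
    r[[id]] <<- rxn(id, stats::setNames(-1, met), lb = lb, ub = ub,
                    subsystem = "exchange", name = paste("exchange of", met))
  }
  ex("glc__D_e", -10); ex("succ_e", 0); ex("ac_e", 0)
  ex("co2_e", -U); ex("o2_e", -U)
  ex("h_e", -U); ex("h2o_e", -U); ex("pi_e", -U)
  used <- unique(unlist(lapply(r, function(x) names(x$stoich))))
  mets <- Filter(function(m) m$id %in% used, core_metabolite_catalog())
  build_model(mets, unname(r), objective_id = "EX_succ_e",
              name = "OXTCA-CORE", version = "oxidative template")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random toy network with a closed-form optimum
#'
#' Builds a substrate uptake chain feeding `n_branches` parallel conversion
#' motifs `s -> y_i p + (1 - y_i) w_i` with seeded yields; each motif is
#' mass-consistent (product plus waste carry the full substrate mass). The
#' optimal objective (maximal product exchange) is `max(y_i) * uptake` and is
#' returned alongside the model.
#'
#' @param seed integer seed.
#' @param n_branches number of parallel branches (0 = single unit-yield chain,
#'   at most 6).
#' @return list with `model`, `optimum`, `uptake` and `yields`.
#' @export
random_toy_network <- function(seed, n_branches = 2) {
  stopifnot(n_branches <= 6)
  with_seed(seed, {
    uptake <- round(stats::runif(1, 1, 10), 3)
    yields <- if (n_branches == 0) 1 else
      round(stats::runif(n_branches, 0.1, 0.9), 3)
    mets <- list(metabolite("s_e", compartment = "e"),
                 metabolite("s_c", compartment = "c"),
                 metabolite("p_c", compartment = "c"),
                 metabolite("p_e", compartment = "e"))
    r <- list(
      rxn("EX_s_e", st(s_e = -1), lb = -uptake),
      rxn("St", st(s_e = -1, s_c = 1)),
      rxn("Pt", st(p_c = -1, p_e = 1)),
      rxn("EX_p_e", st(p_e = -1), lb = 0)
    )
    if (n_branches == 0) {
      r[[length(r) + 1]] <- rxn("B1", st(s_c = -1, p_c = 1))
    } else {
      for (i in seq_len(n_branches)) {
        wi <- paste0("w", i)
        mets[[length(mets) + 1]] <- metabolite(paste0(wi, "_c"),
                                               compartment = "c")
        mets[[length(mets) + 1]] <- metabolite(paste0(wi, "_e"),
                                               compartment = "e")
        stoich <- stats::setNames(c(-1, yields[i], 1 - yields[i]),
                                  c("s_c", "p_c", paste0(wi, "_c")))
        r[[length(r) + 1]] <- rxn(paste0("B", i), stoich)
        r[[length(r) + 1]] <- rxn(paste0("W", i, "t"),
                                  stats::setNames(c(-1, 1),
                                                  paste0(wi, c("_c", "_e"))))
        r[[length(r) + 1]] <- rxn(paste0("EX_", wi, "_e"),
                                  stats::setNames(-1, paste0(wi, "_e")), lb = 0)
      }
    }
    model <- build_model(mets, r, objective_id = "EX_p_e",
                         name = paste0("TOY-", seed))
    list(model = model, optimum = max(yields) * uptake,
         uptake = uptake, yields = yields)
  })
}

#' Synthetic homology-hit table with a planted true EC number
#'
#' Generates a BLAST-outfmt6-like hit table for one query: similarity scores
#' decay geometrically down the ranked list, a seeded subset of hits carries
#' the planted EC, the rest draw decoy ECs from a fixed pool, and subject
#' lineages share more ranks with the query when `taxonomy_bias` is on.
#'
#' @param seed integer seed.
#' @param true_ec the planted EC string.
#' @param n_hits number of hits.
#' @param truth_fraction fraction of hits carrying the true EC, in [0, 1].
#' @param taxonomy_bias if `TRUE`, truth-carrying subjects are taxonomically
#'   close to the query (6-7 shared ranks of 7) and decoys distant (1-3);
#'   otherwise all subjects share a uniform random 1-7 ranks.
#' @param query query id.
#' @return data.frame with columns query, subject, score, ec, lineage.
#' @export
synth_hit_table <- function(seed, true_ec = "1.1.1.37", n_hits = 20,
                            truth_fraction = 0.7, taxonomy_bias = TRUE,
                            query = "cds0001") {
  stopifnot(truth_fraction >= 0, truth_fraction <= 1, n_hits >= 1)
  decoys <- setdiff(c("1.1.1.1", "2.7.1.11", "4.1.1.49", "2.6.1.1",
                      "3.6.1.1", "5.3.1.9"), true_ec)
  ranks <- ASUC_QUERY_LINEAGE
  with_seed(seed, {
    n_true <- round(truth_fraction * n_hits)
    is_true <- rep(FALSE, n_hits)
    if (n_true > 0) is_true[sample.int(n_hits, n_true)] <- TRUE
    score <- 200 * 0.93^(seq_len(n_hits) - 1)
    ec <- ifelse(is_true, true_ec, sample(decoys, n_hits, replace = TRUE))
    shared <- if (taxonomy_bias) {
      ifelse(is_true, sample(6:7, n_hits, replace = TRUE),
             sample(1:3, n_hits, replace = TRUE))
    } else sample(1:7, n_hits, replace = TRUE)
    lineage <- vapply(seq_len(n_hits), function(i) {
      k <- shared[i]
      lin <- c(ranks[seq_len(k)],
               if (k < length(ranks))
                 paste0("alt_", seq_len(length(ranks) - k), "_", i))
      paste(lin, collapse = ";")
    }, "")
    data.frame(query = query,
               subject = sprintf("sbj%04d", seq_len(n_hits)),
               score = score, ec = ec, lineage = lineage,
               stringsAsFactors = FALSE)
  })
}

#' Reference 7-rank lineage of the query strain used by the fixtures
#' @format character vector of ranks, domain first.
#' @export
ASUC_QUERY_LINEAGE <- c(
  "Bacteria", "Pseudomonadota", "Gammaproteobacteria", "Pasteurellales",
  "Pasteurellaceae", "Actinobacillus", "Actinobacillus succinogenes")

#' Manifest describing a generated fixture
#'
#' @param model a generated `cb_model`.
#' @param options named list of generator options used.
#' @return list with fixture id, counts and options; regenerating with the
#'   same options reproduces identical models.
#' @export
fixture_manifest <- function(model, options = list()) {
  list(id = model$annotations$name,
       n_reactions = length(model$reactions),
       n_metabolites = length(model$metabolites),
       n_genes = length(model$genes),
       n_exchanges = length(model$exchanges),
       options = options)
}
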