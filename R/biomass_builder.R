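# Biomass objective construction from macromolecular composition.
#
# Each macromolecule class gets a pseudo-reaction producing one gram of a
# macro pseudo-metabolite (protein_g, glycogen_g, ...); the biomass reaction
# consumes the pseudo-metabolites weighted by dry-weight mass fractions plus
# growth-associated ATP, so one unit of biomass flux drains one gram of dry
# weight per gDCW (verified by a mass audit).

WATER_MASS <- 18.02  # g/mol released per peptide bond

#' Free amino-acid molar masses (g/mol)
#' @export
AA_MOLAR_MASSES <- c(
  gly = 75.07, ala = 89.09, ser = 105.09, pro = 115.13, val = 117.15,
  thr = 119.12, cys = 121.16, leu = 131.17, ile = 131.17, asn = 132.12,
  asp = 133.10, gln = 146.15, lys = 146.19, glu = 147.13, met = 149.21,
  his = 155.15, phe = 165.19, arg = 174.20, tyr = 181.19, trp = 204.23
)

#' Macromolecular dry-weight composition
#'
#' @param protein,dna,rna,lps,phospholipid,peptidoglycan,glycogen,cav mass
#'   fractions in g/gDCW; must be non-negative and sum to 1 (tolerance 1e-6).
#' @param gam growth-associated ATP maintenance, mmol ATP/gDCW.
#' @param ngam non-growth-associated maintenance, mmol ATP/gDCW/h.
#' @return list of class `cb_macro_composition`.
#' @export
macro_composition <- function(protein = 0, dna = 0, rna = 0, lps = 0,
                              phospholipid = 0, peptidoglycan = 0,
                              glycogen = 0, cav = 0, gam = 40, ngam = 0) {
  fr <- c(protein = protein, dna = dna, rna = rna, lps = lps,
          phospholipid = phospholipid, peptidoglycan = peptidoglycan,
          glycogen = glycogen, cav = cav)
  if (any(fr < 0)) stop("mass fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", format(sum(fr)), ")")
  if (gam < 0 || ngam < 0) stop("maintenance terms must be non-negative")
  structure(list(fractions = fr, gam = gam, ngam = ngam),
            class = "cb_macro_composition")
}

# Energy-coupling metabolite ids used by the pseudo-reaction builders.
default_energy_ids <- function() {
  list(atp = "atp_c", adp = "adp_c", pi = "pi_c", h = "h_c", h2o = "h2o_c")
}

#' Protein synthesis pseudo-reaction
#'
#' Builds the reaction draining amino acids into one gram of protein.
#' Coefficients are `f(aa) / sum_i f(i) * (M(i) - M_water)` in mmol per g
#' protein (residue masses, so the polymer mass is exactly one gram).
#' Polymerisation consumes `polymerization_cost` ATP equivalents per peptide
#' bond and releases one condensation water per residue.
#'
#' @param aa_frequencies named molar frequencies summing to 1 (tolerance
#'   1e-6); names must match `aa_masses` (and, with the default masses,
#'   the three-letter lowercase amino-acid codes).
#' @param polymerization_cost ATP equivalents per peptide bond (default 4.3).
#' @param aa_masses molar masses in g/mol for the amino acids used.
#' @param aa_ids metabolite ids of the amino acids (default `<code>__L_c`,
#'   `gly_c` for glycine).
#' @param product_id id of the produced 1-gram protein pseudo-metabolite.
#' @param energy_ids metabolite ids for atp/adp/pi/h/h2o coupling.
#' @return a [reaction()] (irreversible, bounds `[0, UNBOUNDED_FLUX]`).
#' @export
protein_pseudoreaction <- function(aa_frequencies,
                                   polymerization_cost = 4.3,
                                   aa_masses = AA_MOLAR_MASSES[names(aa_frequencies)],
                                   aa_ids = NULL,
                                   product_id = "protein_g",
                                   energy_ids = default_energy_ids()) {
  f <- aa_frequencies
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("amino-acid frequencies must be named")
  if (abs(sum(f) - 1) > 1e-6)
    stop("amino-acid frequencies must sum to 1 (got ", format(sum(f)), ")")
  M <- as.numeric(aa_masses)
  if (any(is.na(M))) stop("missing molar mass for: ",
                          paste(names(f)[is.na(M)], collapse = ", "))
  if (is.null(aa_ids)) {
    aa_ids <- ifelse(names(f) == "gly", "gly_c",
                     paste0(names(f), "__L_c"))
  }
  # mmol residue per gram protein; masses converted g/mol -> g/mmol
  denom <- sum(f * (M - WATER_MASS) / 1000)
  coef <- f / denom
  total <- sum(coef)
  e <- energy_ids
  st <- stats::setNames(-coef, aa_ids)
  st[e$atp] <- -polymerization_cost * total
  st[e$h2o] <- -polymerization_cost * total + total  # condensation water back
  st[e$adp] <- polymerization_cost * total
  st[e$pi]  <- polymerization_cost * total
  st[e$h]   <- polymerization_cost * total
  st[product_id] <- 1
  reaction("PROT_SYN", st[st != 0], lb = 0, ub = UNBOUNDED_FLUX,
           subsystem = "biomass", name = "protein synthesis (1 g)")
}

#' Cofactors-and-vitamins pseudo-reaction
#'
#' Each small molecule contributes an equal mass share to one gram of the
#' CAV pool: for `n` species, `coeff(i) = (1/n) / M(i)` mmol per g with
#' masses in g/mmol.
#'
#' @param cav_metabolites named numeric vector metabolite-id -> molar mass
#'   (g/mol).
#' @param product_id produced 1-gram pseudo-metabolite id.
#' @return a [reaction()].
#' @export
cav_pseudoreaction <- function(cav_metabolites, product_id = "cav_g") {
  M <- as.numeric(cav_metabolites)
  if (!length(M) || is.null(names(cav_metabolites)))
    stop("cav_metabolites must be a named vector of molar masses")
  if (any(!is.finite(M)) || any(M <= 0))
    stop("missing or non-positive molar mass for: ",
         paste(names(cav_metabolites)[!is.finite(M) | M <= 0], collapse = ", "))
  n <- length(M)
  coef <- (1 / n) / (M / 1000)   # mmol per gram CAV
  st <- stats::setNames(-coef, names(cav_metabolites))
  st[product_id] <- 1
  reaction("CAV_SYN", st, lb = 0, ub = UNBOUNDED_FLUX,
           subsystem = "biomass", name = "cofactor and vitamin pool (1 g)")
}

#' Assemble the biomass reaction
#'
#' Consumes the macromolecule pseudo-metabolites weighted by mass fraction
#' plus growth-associated ATP (GAM); one unit of flux drains one gram of dry
#' weight. Macro classes with zero fraction need no pseudo-reaction.
#'
#' @param composition a [macro_composition()].
#' @param macro_reactions named list (by macro class) of the pseudo-reactions
#'   producing the corresponding 1-gram pseudo-metabolites.
#' @param id reaction id for the biomass reaction.
#' @param energy_ids metabolite ids for the GAM coupling.
#' @return a [reaction()] with flux in 1/h.
#' @export
assemble_biomass <- function(composition, macro_reactions,
                             id = "BIOMASS", energy_ids = default_energy_ids()) {
  stopifnot(inherits(composition, "cb_macro_composition"))
  fr <- composition$fractions
  active <- names(fr)[fr > 0]
  missing <- setdiff(active, names(macro_reactions))
  if (length(missing))
    stop("no macro pseudo-reaction supplied for: ",
         paste(missing, collapse = ", "))
  st <- stats::setNames(numeric(0), character(0))
  for (m in active) {
    rx <- macro_reactions[[m]]
    # the 1-gram pseudo-product follows the "_g" id convention; energy
    # byproducts (adp, pi, h) are also positive and must not be drained
    prod_id <- names(rx$stoich)[rx$stoich > 0 & endsWith(names(rx$stoich), "_g")]
    if (length(prod_id) != 1L)
      stop("macro pseudo-reaction for ", m,
           " must produce exactly one '*_g' pseudo-metabolite")
    st[prod_id] <- -fr[[m]]
  }
  gam <- composition$gam
  if (gam > 0) {
    e <- energy_ids
    st[e$atp] <- (if (e$atp %in% names(st)) st[[e$atp]] else 0) - gam
    st[e$h2o] <- (if (e$h2o %in% names(st)) st[[e$h2o]] else 0) - gam
    st[e$adp] <- (if (e$adp %in% names(st)) st[[e$adp]] else 0) + gam
    st[e$pi]  <- (if (e$pi %in% names(st)) st[[e$pi]] else 0) + gam
    st[e$h]   <- (if (e$h %in% names(st)) st[[e$h]] else 0) + gam
  }
  reaction(id, st, lb = 0, ub = UNBOUNDED_FLUX,
           subsystem = "biomass", name = "biomass assembly (1 gDCW)")
}

#' Mass audit of a pseudo-reaction
#'
#' Net mass drained into the pseudo-products: consumed minus produced mass
#' over metabolites with known molar mass (pseudo-metabolites without mass
#' are the audited products). For a correctly built macromolecule
#' pseudo-reaction this equals 1 g; for an assembled biomass, 1 gDCW.
#'
#' @param rxn a [reaction()].
#' @param masses named molar masses (g/mol) for the real metabolites.
#' @return net consumed mass in grams per unit flux.
#' @export
mass_audit <- function(rxn, masses) {
  st <- rxn$stoich
  known <- names(st)[names(st) %in% names(masses) & is.finite(masses[names(st)])]
  -sum(st[known] * masses[known] / 1000)
}

#' Mass audit of an assembled biomass
#'
#' Total dry mass drained per unit biomass flux: each macro pseudo-metabolite
#' consumed by the biomass reaction carries the net mass its pseudo-reaction
#' drains per gram; the GAM hydrolysis is mass-neutral.
#'
#' @param composition the [macro_composition()] used.
#' @param macro_reactions the macro pseudo-reactions used.
#' @param masses named molar masses (g/mol) of the real metabolites.
#' @return grams of dry weight per gDCW (1 within 0.1% for a sound biomass).
#' @export
biomass_mass_audit <- function(composition, macro_reactions, masses) {
  fr <- composition$fractions
  active <- names(fr)[fr > 0]
  sum(vapply(active, function(m)
    fr[[m]] * mass_audit(macro_reactions[[m]], masses), 0))
}
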