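# Elemental formula handling: parsing, molar mass, composition arithmetic.

ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, Na = 22.99, Mg = 24.305, Ca = 40.078, Fe = 55.845,
  Cl = 35.45, Zn = 65.38, Mn = 54.938, Cu = 63.546, Co = 58.933,
  Mo = 95.95, Se = 78.971
)

#' Parse a chemical formula string
#'
#' Turns `"C6H12O6"` into a named integer vector of element counts. An empty
#' or `NA` formula parses to an empty vector (composition unknown).
#'
#' @param formula formula string, e.g. `"C21H26N7O14P2"`.
#' @return named numeric vector element -> count.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Molar mass of a formula
#'
#' @param formula formula string or parsed element-count vector.
#' @return mass in g/mol.
#' @examples
#' molar_mass("C4H6O4")   # succinic acid, 118.09
#' @export
molar_mass <- function(formula) {
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  if (!length(comp)) return(NA_real_)
  unknown <- setdiff(names(comp), names(ATOMIC_WEIGHTS))
  if (length(unknown)) stop("no atomic weight for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(comp * ATOMIC_WEIGHTS[names(comp)])
}

# Sum element compositions weighted by coefficients; list of parsed vectors.
combine_compositions <- function(comps, coefs) {
  acc <- stats::setNames(numeric(0), character(0))
  for (i in seq_along(comps)) {
    ci <- comps[[i]]
    if (!length(ci)) next
    for (el in names(ci)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + coefs[i] * ci[[el]]
    }
  }
  acc[abs(acc) > 1e-9, drop = FALSE]
}

# Degree of reduction per molecule (electrons available to O2), using the
# standard valences C4 H1 O-2 N-3 P5 S6 and zero for charge-balancing H+.
degree_of_reduction <- function(formula, charge = 0) {
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  if (!length(comp)) return(NA_real_)
  val <- c(C = 4, H = 1, O = -2, N = -3, P = 5, S = 6)
  g <- 0
  for (el in names(comp)) {
    if (el %in% names(val)) g <- g + val[[el]] * comp[[el]]
  }
  g - charge
}

# Fixed molar-mass table for yield reporting (g/mol), matching the common
# fermentation species; computed values from formulas agree to < 0.1%.
YIELD_MOLAR_MASSES <- c(
  glucose = 180.16, sorbitol = 182.17, xylose = 150.13,
  succinate = 118.09, acetate = 60.05, formate = 46.03, ethanol = 46.07
)
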