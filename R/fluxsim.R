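# Flux simulation: FBA, parsimonious FBA, flux variability analysis,
# theoretical maximum yields and yield arithmetic.

# Assemble the LP data (S, bounds, objective vector) for a model.
model_lp_data <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  b <- reaction_bounds(model)
  list(S = S, lb = b$lb, ub = b$ub, ids = b$id)
}

flux_solution <- function(status, objective = NA_real_, fluxes = NULL,
                          ids = character()) {
  if (is.null(fluxes)) fluxes <- stats::setNames(rep(NA_real_, length(ids)), ids)
  structure(list(status = status, objective = objective, fluxes = fluxes,
                 total_abs_flux = if (all(is.finite(fluxes)))
                   sum(abs(fluxes)) else NA_real_),
            class = "cb_flux_solution")
}

#' @export
print.cb_flux_solution <- function(x, ...) {
  cat("<flux solution> status:", x$status,
      " objective:", format(x$objective, digits = 6),
      " total |v|:", format(x$total_abs_flux, digits = 6), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves `max (or min) v_objective` subject to `S v = 0` and the model's
#' flux bounds.
#'
#' @param model a `cb_model` with an objective set (or `objective` given).
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @return a `cb_flux_solution` with `status` (`"optimal"`/`"infeasible"`),
#'   `objective`, the flux vector and the total absolute flux.
#' @export
fba <- function(model, objective = model$objective_id,
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective) || is.na(objective))
    stop("no objective set; use set_objective() first")
  if (!objective %in% reaction_ids(model))
    stop("unknown objective reaction: ", objective)
  lpd <- model_lp_data(model)
  obj <- as.numeric(lpd$ids == objective)
  res <- solve_lp(obj, lpd$S, rep(0, nrow(lpd$S)), lpd$lb, lpd$ub,
                  maximize = direction == "max")
  if (res$status != "optimal") return(flux_solution(res$status, ids = lpd$ids))
  v <- stats::setNames(res$x, lpd$ids)
  resid <- max(abs(lpd$S %*% res$x))
  if (resid > 1e-6) stop("steady-state residual above tolerance: ", resid)
  flux_solution("optimal", res$objective, v)
}

#' Parsimonious flux balance analysis
#'
#' Fixes the FBA optimum (at 100% of its value) and minimises the total
#' absolute flux by splitting every reaction into non-negative forward and
#' backward parts.
#'
#' @inheritParams fba
#' @return a `cb_flux_solution`; its `objective` equals the FBA optimum and
#'   `total_abs_flux` is minimal among alternative optima.
#' @export
pfba <- function(model, objective = model$objective_id) {
  base <- fba(model, objective, "max")
  if (base$status != "optimal") return(base)
  lpd <- model_lp_data(model)
  n <- length(lpd$ids)
  # columns: forward then backward halves; v = f - b
  S2 <- cbind(lpd$S, -lpd$S)
  obj_row <- c(as.numeric(lpd$ids == objective),
               -as.numeric(lpd$ids == objective))
  A <- rbind(S2, obj_row)
  rhs <- c(rep(0, nrow(lpd$S)), base$objective)
  lb <- rep(0, 2 * n)
  ub <- c(pmax(lpd$ub, 0), pmax(-lpd$lb, 0))
  # a flux forced positive (lb>0) or negative (ub<0) keeps its floor
  lbf <- pmax(lpd$lb, 0); lbb <- pmax(-lpd$ub, 0)
  res <- solve_lp(rep(1, 2 * n), A, rhs, c(lbf, lbb), ub, maximize = FALSE)
  if (res$status != "optimal")
    stop("pFBA restriction infeasible; numerical tolerance issue")
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], lpd$ids)
  out <- flux_solution("optimal", base$objective, v)
  out
}

#' Flux variability analysis
#'
#' For each reaction, minimises and maximises its flux while the objective
#' reaction is held at at least `fraction` of its FBA optimum.
#'
#' @param model a `cb_model`.
#' @param fraction fraction-of-optimum gamma in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @param objective objective reaction id.
#' @return data.frame with reaction, vmin, vmax, fraction and span
#'   (`vmax - vmin`).
#' @export
fva <- function(model, fraction = 0.95, reactions = NULL,
                objective = model$objective_id) {
  stopifnot(fraction > 0, fraction <= 1)
  base <- fba(model, objective, "max")
  if (base$status != "optimal") stop("FVA base problem is ", base$status)
  lpd <- model_lp_data(model)
  iobj <- match(objective, lpd$ids)
  # the objective is a single reaction: the fraction constraint is a bound
  floor_v <- fraction * base$objective
  lb <- lpd$lb; ub <- lpd$ub
  lb[iobj] <- max(lb[iobj], min(floor_v, ub[iobj]))
  if (is.null(reactions)) reactions <- lpd$ids
  idx <- match(reactions, lpd$ids)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  vmin <- numeric(length(idx)); vmax <- numeric(length(idx))
  zero <- rep(0, nrow(lpd$S))
  for (k in seq_along(idx)) {
    obj <- as.numeric(seq_along(lpd$ids) == idx[k])
    lo <- solve_lp(obj, lpd$S, zero, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, lpd$S, zero, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem infeasible for ", lpd$ids[idx[k]])
    vmin[k] <- lo$objective; vmax[k] <- hi$objective
  }
  data.frame(reaction = lpd$ids[idx], vmin = vmin, vmax = vmax,
             fraction = fraction, span = vmax - vmin, row.names = NULL)
}

#' Flux span of an FVA range
#'
#' @param range data.frame from [fva()] (or any with vmin/vmax columns).
#' @return `vmax - vmin`, named by reaction when available.
#' @export
flux_span <- function(range) {
  s <- range$vmax - range$vmin
  if (!is.null(range$reaction)) names(s) <- range$reaction
  s
}

#' Convert a molar yield to a mass yield
#'
#' @param y_mol yield in mol product per mol substrate.
#' @param m_product,m_substrate molar masses in g/mol (must be positive).
#' @return yield in g product per g substrate.
#' @examples
#' mol_to_mass_yield(0.63, 118.09, 180.16)   # 0.41 g/g
#' @export
mol_to_mass_yield <- function(y_mol, m_product, m_substrate) {
  if (!is.finite(m_product) || !is.finite(m_substrate) ||
      m_product <= 0 || m_substrate <= 0)
    stop("molar masses must be positive")
  y_mol * m_product / m_substrate
}

# Reporting molar mass of the species behind an exchange reaction: the
# neutral (fully protonated) form, matching how fermentation yields are
# quoted (succinic acid 118.09, not the dianion).
exchange_species_mass <- function(model, ex_id) {
  met_id <- names(model$reactions[[ex_id]]$stoich)
  m <- model$metabolites[[met_id]]
  comp <- parse_formula(m$formula)
  if (!length(comp)) return(NA_real_)
  comp["H"] <- (if ("H" %in% names(comp)) comp[["H"]] else 0) - m$charge
  molar_mass(comp)
}

#' Maximum theoretical product yield
#'
#' Fixes the substrate uptake to a unit basis, removes biomass formation and
#' any forced ATP maintenance (the maintenance reaction keeps its hydrolysis
#' capacity so surplus fermentative ATP can be dissipated), and maximises the
#' product exchange flux.
#'
#' @param model a `cb_model`.
#' @param product_exchange,substrate_exchange exchange reaction ids.
#' @param substrate_rate uptake basis in mmol/gDCW/h (default 1).
#' @param biomass_id biomass reaction to silence (default: model objective;
#'   `NA` to skip).
#' @param atpm_id maintenance reaction whose lower bound is dropped to zero
#'   (`NA` or absent id to skip).
#' @return list of class `cb_yield` with `y_mol` (mol/mol), `y_mass` (g/g,
#'   from the neutral-species molar masses), ids, basis and the underlying
#'   solution.
#' @export
max_theoretical_yield <- function(model, product_exchange, substrate_exchange,
                                  substrate_rate = 1,
                                  biomass_id = model$objective_id,
                                  atpm_id = "ATPM") {
  for (id in c(product_exchange, substrate_exchange)) {
    if (!id %in% model$exchanges) stop("not an exchange reaction: ", id)
  }
  sub <- model$reactions[[substrate_exchange]]
  if (sub$lb >= 0)
    stop("substrate exchange ", substrate_exchange,
         " is closed for uptake; open it in the medium first")
  m <- set_reaction_bounds(model, substrate_exchange,
                           -substrate_rate, -substrate_rate)
  if (!is.null(biomass_id) && !is.na(biomass_id) &&
      biomass_id %in% reaction_ids(m)) {
    m <- set_reaction_bounds(m, biomass_id, 0, 0)
  }
  if (!is.null(atpm_id) && !is.na(atpm_id) && atpm_id %in% reaction_ids(m)) {
    m <- set_reaction_bounds(m, atpm_id, 0, m$reactions[[atpm_id]]$ub)
  }
  sol <- fba(m, product_exchange, "max")
  if (sol$status != "optimal")
    stop("theoretical-yield LP is ", sol$status)
  y_mol <- sol$objective / substrate_rate
  mp <- exchange_species_mass(model, product_exchange)
  ms <- exchange_species_mass(model, substrate_exchange)
  y_mass <- if (is.finite(mp) && is.finite(ms))
    mol_to_mass_yield(y_mol, mp, ms) else NA_real_
  structure(list(product = product_exchange, substrate = substrate_exchange,
                 y_mol = y_mol, y_mass = y_mass, basis = "theoretical-max",
                 m_product = mp, m_substrate = ms, solution = sol),
            class = "cb_yield")
}

#' @export
print.cb_yield <- function(x, ...) {
  cat("<yield> ", x$product, "/", x$substrate, " (", x$basis, "): ",
      format(x$y_mol, digits = 4), " mol/mol",
      if (is.finite(x$y_mass))
        paste0(" = ", format(x$y_mass, digits = 3), " g/g") else "",
      "\n", sep = "")
  invisible(x)
}
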