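# Network curation checks: elemental/charge balancing with proton/water
# repair suggestions, dead-end metabolite detection, blocked reactions.

#' Elemental and charge balance of one reaction
#'
#' Residuals are products minus reactants per element and for charge.
#' Exchange reactions and biomass-subsystem pseudo-reactions are reported as
#' `"excluded"`; reactions touching a metabolite without a formula as
#' `"unverifiable"` (listing the offenders).
#'
#' @param model a `cb_model`.
#' @param rxn_id reaction id.
#' @return list of class `cb_balance_report`: `rxn_id`, `status`
#'   (`"balanced"`, `"imbalanced"`, `"excluded"`, `"unverifiable"`),
#'   `element_residual`, `charge_residual`, `compartment`, `missing`,
#'   `suggested_fix`.
#' @export
element_balance <- function(model, rxn_id) {
  if (!rxn_id %in% reaction_ids(model)) stop("unknown reaction: ", rxn_id)
  r <- model$reactions[[rxn_id]]
  rep0 <- function(status, element = NULL, charge = NA_real_,
                   missing = character(), fix = list()) {
    structure(list(rxn_id = rxn_id, status = status,
                   element_residual = element, charge_residual = charge,
                   compartment = majority_compartment(model, r),
                   missing = missing, suggested_fix = fix),
              class = "cb_balance_report")
  }
  if (rxn_id %in% model$exchanges || identical(r$subsystem, "biomass"))
    return(rep0("excluded"))
  mets <- model$metabolites[names(r$stoich)]
  comps <- lapply(mets, function(m) parse_formula(m$formula))
  nofml <- names(r$stoich)[vapply(comps, length, 1L) == 0]
  if (length(nofml)) return(rep0("unverifiable", missing = nofml))
  elem <- combine_compositions(comps, as.numeric(r$stoich))
  charge <- sum(vapply(mets, `[[`, 0, "charge") * as.numeric(r$stoich))
  status <- if (!length(elem) && abs(charge) < 1e-9) "balanced" else "imbalanced"
  rep <- rep0(status, element = elem, charge = charge)
  if (status == "imbalanced") rep$suggested_fix <- suggest_balancing(rep)
  rep
}

majority_compartment <- function(model, r) {
  comps <- vapply(model$metabolites[names(r$stoich)], `[[`, "", "compartment")
  names(sort(table(comps), decreasing = TRUE))[1]
}

#' Proton/water repair suggestion for an imbalanced reaction
#'
#' Solves the two-unknown integer system in (water, proton) that zeroes the
#' H, O and charge residuals. When the residual involves any other element
#' no proton/water combination can help and the report is flagged a
#' structural imbalance.
#'
#' @param report a `cb_balance_report` with nonzero residuals.
#' @return list of `(metabolite, coefficient)` pairs to add to the products
#'   (negative coefficient = add to reactants), empty when no repair exists;
#'   attribute `structural` is `TRUE` for non-H/O/charge residuals.
#' @export
suggest_balancing <- function(report) {
  el <- report$element_residual
  ch <- report$charge_residual
  other <- setdiff(names(el), c("H", "O"))
  if (length(other)) {
    out <- list()
    attr(out, "structural") <- TRUE
    return(out)
  }
  rH <- if ("H" %in% names(el)) el[["H"]] else 0
  rO <- if ("O" %in% names(el)) el[["O"]] else 0
  # adding n_w water and n_h protons to the products shifts residuals by
  # (H: n_h + 2 n_w, O: n_w, charge: n_h)
  n_w <- -rO
  n_h <- -ch
  if (abs(n_h + 2 * n_w + rH) > 1e-9 ||
      abs(n_w - round(n_w)) > 1e-9 || abs(n_h - round(n_h)) > 1e-9) {
    out <- list()
    attr(out, "structural") <- FALSE
    return(out)
  }
  comp <- report$compartment
  out <- list()
  if (abs(n_w) > 1e-9)
    out[[length(out) + 1]] <- list(metabolite = paste0("h2o_", comp),
                                   coefficient = n_w)
  if (abs(n_h) > 1e-9)
    out[[length(out) + 1]] <- list(metabolite = paste0("h_", comp),
                                   coefficient = n_h)
  attr(out, "structural") <- FALSE
  out
}

#' Balance summary for a whole model
#'
#' @param model a `cb_model`.
#' @return data.frame with one row per reaction: status and the residual
#'   summary (element residuals formatted `El:count`).
#' @export
balance_table <- function(model) {
  rows <- lapply(reaction_ids(model), function(id) {
    b <- element_balance(model, id)
    res <- if (is.null(b$element_residual) || !length(b$element_residual)) ""
    else paste(names(b$element_residual), b$element_residual,
               sep = ":", collapse = ",")
    data.frame(rxn_id = id, status = b$status, element_residual = res,
               charge_residual = b$charge_residual,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dead-end metabolite detection
#'
#' Purely topological: a metabolite is a dead end when, over the sign
#' pattern of the stoichiometric matrix under the reaction reversibilities
#' (exchanges included), it cannot be both produced and consumed.
#'
#' @param model a `cb_model`.
#' @return data.frame with metabolite and mode
#'   (`"only-produced"`, `"only-consumed"`, `"orphan"`); zero rows for a
#'   gap-free network.
#' @export
find_dead_ends <- function(model) {
  producers <- consumers <- stats::setNames(integer(length(model$metabolites)),
                                            metabolite_ids(model))
  for (r in model$reactions) {
    # exchanges count both ways: a closed uptake is a medium choice, not a
    # network gap
    is_ex <- r$id %in% model$exchanges
    fwd <- is_ex || r$ub > 1e-12
    bwd <- is_ex || r$lb < -1e-12
    for (m in names(r$stoich)) {
      cc <- r$stoich[[m]]
      if ((cc > 0 && fwd) || (cc < 0 && bwd)) producers[m] <- producers[m] + 1L
      if ((cc < 0 && fwd) || (cc > 0 && bwd)) consumers[m] <- consumers[m] + 1L
    }
  }
  mode <- ifelse(producers > 0 & consumers == 0, "only-produced",
          ifelse(consumers > 0 & producers == 0, "only-consumed",
          ifelse(producers == 0 & consumers == 0, "orphan", NA)))
  keep <- !is.na(mode)
  data.frame(metabolite = metabolite_ids(model)[keep], mode = mode[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Blocked reactions under a medium
#'
#' Reactions whose flux interval is exactly `[0, 0]` with no optimality
#' constraint, i.e. that can carry no steady-state flux at all under the
#' given bounds.
#'
#' @param model a `cb_model`.
#' @param medium optional [medium()] applied first.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  lpd <- model_lp_data(model)
  zero <- rep(0, nrow(lpd$S))
  feas <- solve_lp(rep(0, length(lpd$ids)), lpd$S, zero, lpd$lb, lpd$ub)
  if (feas$status != "optimal") stop("model infeasible under this medium")
  blocked <- character(0)
  for (k in seq_along(lpd$ids)) {
    obj <- as.numeric(seq_along(lpd$ids) == k)
    hi <- solve_lp(obj, lpd$S, zero, lpd$lb, lpd$ub, maximize = TRUE)
    if (abs(hi$objective) > 1e-9) next
    lo <- solve_lp(obj, lpd$S, zero, lpd$lb, lpd$ub, maximize = FALSE)
    if (abs(lo$objective) <= 1e-9) blocked <- c(blocked, lpd$ids[k])
  }
  blocked
}
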