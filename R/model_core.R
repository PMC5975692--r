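# In-memory constraint-based model: metabolites, reactions, media, bounds.
#
# Sign conventions follow the usual COBRA ones: negative stoichiometric
# coefficients consume, exchange reactions touch exactly one metabolite, a
# negative exchange flux is uptake, and "unconstrained" bounds use a finite
# +-1000 mmol/gDCW/h sentinel so every LP stays bounded.

#' Default magnitude used for unconstrained flux bounds (mmol/gDCW/h)
#' @export
UNBOUNDED_FLUX <- 1000

#' Create a metabolite
#'
#' @param id unique metabolite id (convention: `<name>_<compartment>`).
#' @param name human-readable name.
#' @param formula elemental formula string (may be empty when unknown).
#' @param charge integer formal charge.
#' @param compartment compartment token (e.g. `"c"`, `"e"`).
#' @return object of class `cb_metabolite`.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0,
                       compartment = sub("^.*_", "", id)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  comp <- parse_formula(formula)
  if (any(comp < 0)) stop("negative element count in formula for ", id)
  structure(list(id = id, name = name, formula = formula, charge = charge,
                 compartment = compartment),
            class = "cb_metabolite")
}

#' Create a reaction
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector metabolite-id -> signed coefficient
#'   (negative = consumed).
#' @param lb,ub flux bounds in mmol/gDCW/h (biomass in 1/h).
#' @param gene_association boolean gene expression text (`"(g1 and g2) or g3"`),
#'   may be empty.
#' @param ec character vector of EC numbers.
#' @param subsystem subsystem token.
#' @param name human-readable name.
#' @return object of class `cb_reaction`; `reversible` is derived as `lb < 0`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = UNBOUNDED_FLUX,
                     gene_association = "", ec = character(),
                     subsystem = "", name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoich) || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction ", id, ": stoichiometry must be a non-empty named vector")
  if (anyDuplicated(names(stoich)))
    stop("reaction ", id, ": duplicated metabolite in stoichiometry")
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stop("reaction ", id, ": all coefficients are zero")
  if (lb > ub) stop("reaction ", id, ": lower bound ", lb,
                    " exceeds upper bound ", ub)
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gene_association = gene_association,
                 ec = ec, subsystem = subsystem),
            class = "cb_reaction")
}

is_reversible <- function(rxn) rxn$lb < 0

# Gene ids mentioned in a boolean gene-association string.
gpr_genes <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(gpr)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", gpr), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Assemble and validate a constraint-based model
#'
#' Checks id uniqueness, dangling metabolite references and the objective,
#' identifies exchange reactions (those touching exactly one metabolite) and
#' builds index structures.
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective reaction (may be `NA` for a model
#'   loaded without an objective; simulation then refuses until it is set).
#' @param name,version model annotations.
#' @param sentinel magnitude standing for an unconstrained bound.
#' @return object of class `cb_model`.
#' @export
build_model <- function(metabolites, reactions, objective_id,
                        name = "model", version = "0", sentinel = UNBOUNDED_FLUX) {
  if (!length(reactions)) stop("empty model: no reactions")
  if (!length(metabolites)) stop("empty model: no metabolites")
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  for (r in reactions) {
    missing <- setdiff(names(r$stoich), met_ids)
    if (length(missing))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  if (!is.na(objective_id) && !objective_id %in% rxn_ids)
    stop("objective reaction not in model: ", objective_id)
  genes <- sort(unique(unlist(lapply(reactions, function(r)
    gpr_genes(r$gene_association)))))
  exchanges <- rxn_ids[vapply(reactions, function(r)
    length(r$stoich) == 1L, TRUE)]
  structure(list(
    metabolites = stats::setNames(metabolites, met_ids),
    reactions = stats::setNames(reactions, rxn_ids),
    genes = genes,
    objective_id = objective_id,
    exchanges = exchanges,
    sentinel = sentinel,
    annotations = list(name = name, version = version)
  ), class = "cb_model")
}

#' @export
print.cb_model <- function(x, ...) {
  cat("<cb_model> ", x$annotations$name, "\n",
      "  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n",
      "  exchanges: ", length(x$exchanges),
      "  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

metabolite_ids <- function(model) names(model$metabolites)
reaction_ids <- function(model) names(model$reactions)

#' Reaction bounds of a model
#'
#' @param model a `cb_model`.
#' @return data.frame with id, lb, ub, reversible.
#' @export
reaction_bounds <- function(model) {
  data.frame(
    id = reaction_ids(model),
    lb = vapply(model$reactions, `[[`, 0, "lb"),
    ub = vapply(model$reactions, `[[`, 0, "ub"),
    reversible = vapply(model$reactions, is_reversible, TRUE),
    row.names = NULL
  )
}

#' Sparse stoichiometric matrix
#'
#' @param model a `cb_model`.
#' @return `dgCMatrix` (metabolites x reactions) of signed coefficients.
#' @export
stoich_matrix <- function(model) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Define a growth medium
#'
#' A medium maps exchange-reaction ids to `(lower, upper)` flux bounds;
#' a negative lower bound permits uptake.
#'
#' @param ... named arguments, each a numeric vector `c(lb, ub)`.
#' @return named list of bound pairs, class `cb_medium`.
#' @examples
#' medium(EX_glc__D_e = c(-8, 0), EX_co2_e = c(-UNBOUNDED_FLUX, UNBOUNDED_FLUX))
#' @export
medium <- function(...) {
  m <- list(...)
  if (length(m) && (is.null(names(m)) || any(!nzchar(names(m)))))
    stop("medium entries must be named by exchange reaction id")
  for (id in names(m)) {
    b <- m[[id]]
    if (!is.numeric(b) || length(b) != 2L || b[1] > b[2])
      stop("medium entry ", id, " must be c(lb, ub) with lb <= ub")
  }
  structure(m, class = "cb_medium")
}

#' Apply a medium to a model
#'
#' Overwrites exchange bounds with the medium's; every exchange absent from
#' the medium is closed for uptake (lower bound 0) but left open for
#' secretion. Idempotent for a fixed medium.
#'
#' @param model a `cb_model`.
#' @param medium a [medium()] or plain named list of `c(lb, ub)` pairs.
#' @return modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  med <- unclass(medium)
  bad <- setdiff(names(med), model$exchanges)
  if (length(bad))
    stop("medium entries are not exchange reactions: ",
         paste(bad, collapse = ", "))
  for (id in model$exchanges) {
    r <- model$reactions[[id]]
    if (id %in% names(med)) {
      r$lb <- as.numeric(med[[id]][1]); r$ub <- as.numeric(med[[id]][2])
    } else {
      r$lb <- 0
      r$ub <- max(r$ub, 0)
    }
    model$reactions[[id]] <- r
  }
  model
}

#' Set bounds of one reaction
#'
#' @param model a `cb_model`.
#' @param rxn_id reaction id.
#' @param lb,ub new bounds, `lb <= ub`.
#' @return modified copy of the model (the reversibility flag follows the
#'   new lower bound).
#' @export
set_reaction_bounds <- function(model, rxn_id, lb, ub) {
  if (!rxn_id %in% reaction_ids(model))
    stop("unknown reaction: ", rxn_id)
  if (lb > ub) stop("reaction ", rxn_id, ": lower bound ", lb,
                    " exceeds upper bound ", ub)
  model$reactions[[rxn_id]]$lb <- as.numeric(lb)
  model$reactions[[rxn_id]]$ub <- as.numeric(ub)
  model
}

#' Set the objective reaction
#'
#' @param model a `cb_model`.
#' @param rxn_id id of the new objective reaction.
#' @return modified copy of the model.
#' @export
set_objective <- function(model, rxn_id) {
  if (!rxn_id %in% reaction_ids(model))
    stop("unknown reaction: ", rxn_id)
  model$objective_id <- rxn_id
  model
}

# The exchange reaction id of a metabolite, or NA.
exchange_of <- function(model, met_id) {
  for (id in model$exchanges) {
    if (names(model$reactions[[id]]$stoich) == met_id) return(id)
  }
  NA_character_
}
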