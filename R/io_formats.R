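# Model input/output: SBML Level 3 + FBC (write and read), legacy Level 2
# read (kinetic-law bound parameters), a tabular model dialect for fixtures,
# media/scenario configs (YAML) and model statistics.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Model statistics
#'
#' Counts unique genes, reactions and metabolites. Because a printed
#' metabolite tally depends on whether species are counted per compartment
#' or as base compounds, both tallies are reported.
#'
#' @param model a `cb_model`.
#' @return list of class `cb_model_stats` with `n_genes`, `n_reactions`,
#'   `n_metabolites` (unique species ids, compartment included) and
#'   `n_metabolites_base` (compartment suffix stripped).
#' @export
model_stats <- function(model) {
  ids <- metabolite_ids(model)
  base <- sub("_[a-zA-Z0-9]+$", "", ids)
  structure(list(n_genes = length(model$genes),
                 n_reactions = length(model$reactions),
                 n_metabolites = length(unique(ids)),
                 n_metabolites_base = length(unique(base))),
            class = "cb_model_stats")
}

#' @export
print.cb_model_stats <- function(x, ...) {
  cat("genes: ", x$n_genes, "  reactions: ", x$n_reactions,
      "  metabolites: ", x$n_metabolites,
      " (", x$n_metabolites_base, " ignoring compartments)\n", sep = "")
  invisible(x)
}

# ---- tabular model dialect -------------------------------------------------

format_equation <- function(r) {
  side <- function(ids, coefs) {
    if (!length(ids)) return("")
    paste(ifelse(abs(coefs - 1) < 1e-12, ids,
                 paste(format(coefs, digits = 12, trim = TRUE), ids)),
          collapse = " + ")
  }
  neg <- r$stoich < 0
  lhs <- side(names(r$stoich)[neg], -r$stoich[neg])
  rhs <- side(names(r$stoich)[!neg], r$stoich[!neg])
  arrow <- if (r$lb < 0 && nzchar(rhs)) "<->" else "->"
  paste(lhs, arrow, rhs)
}

parse_equation <- function(eq, line = NA) {
  err <- function(...) stop("line ", line, ": ", ..., call. = FALSE)
  rev <- grepl("<->", eq, fixed = TRUE)
  parts <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(parts) > 2) err("multiple arrows in equation: ", eq)
  lhs <- trimws(parts[1])
  rhs <- if (length(parts) == 2) trimws(parts[2]) else ""
  if (!nzchar(lhs)) err("equation has no reactants: ", eq)
  if (rev && !nzchar(rhs)) err("reversible equation has no products: ", eq)
  parse_side <- function(s, sign) {
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (tm in trimws(terms)) {
      if (!nzchar(tm)) err("empty term in equation: ", eq)
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1) { cf <- 1; id <- toks }
      else if (length(toks) == 2) {
        cf <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(cf)) err("bad coefficient '", toks[1], "' in: ", eq)
        id <- toks[2]
      } else err("cannot parse term '", tm, "' in: ", eq)
      out[id] <- (if (id %in% names(out)) out[[id]] else 0) + sign * cf
    }
    out
  }
  l <- parse_side(lhs, -1)
  r <- parse_side(rhs, +1)
  both <- c(l, r[setdiff(names(r), names(l))])
  for (id in intersect(names(l), names(r))) both[id] <- l[[id]] + r[[id]]
  list(stoich = both[both != 0], reversible = rev)
}

#' Write a model as a tabular (TSV) file pair
#'
#' The reaction table has columns rxn_id, equation, lb, ub, genes, ec,
#' subsystem; header comment lines (`#!`) carry the model name and
#' objective. A companion `*_metabolites.tsv` stores id, name, formula,
#' charge and compartment so the dialect is lossless.
#'
#' @param model a `cb_model`.
#' @param path output path for the reaction table.
#' @param metabolites_path companion metabolite table path (default derived
#'   from `path`).
#' @return `path`, invisibly.
#' @export
write_model_table <- function(model, path,
                              metabolites_path = default_met_path(path)) {
  rxn <- data.frame(
    rxn_id = reaction_ids(model),
    equation = vapply(model$reactions, format_equation, ""),
    lb = vapply(model$reactions, `[[`, 0, "lb"),
    ub = vapply(model$reactions, `[[`, 0, "ub"),
    genes = vapply(model$reactions, `[[`, "", "gene_association"),
    ec = vapply(model$reactions, function(r) paste(r$ec, collapse = ";"), ""),
    subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#! name: ", model$annotations$name),
               paste0("#! version: ", model$annotations$version),
               paste0("#! objective: ", model$objective_id)), con)
  utils::write.table(rxn, con, sep = "\t", quote = FALSE, row.names = FALSE)
  met <- data.frame(
    id = metabolite_ids(model),
    name = vapply(model$metabolites, `[[`, "", "name"),
    formula = vapply(model$metabolites, `[[`, "", "formula"),
    charge = vapply(model$metabolites, `[[`, 0, "charge"),
    compartment = vapply(model$metabolites, `[[`, "", "compartment"),
    stringsAsFactors = FALSE
  )
  utils::write.table(met, metabolites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_met_path <- function(path)
  paste0(sub("\\.tsv$", "", path), "_metabolites.tsv")

#' Read a model from the tabular dialect
#'
#' @param path reaction table written by [write_model_table()] (or
#'   hand-written in the same dialect).
#' @param metabolites_path companion metabolite table; when absent,
#'   metabolites are inferred from the equations with empty formulas.
#' @return a `cb_model`.
#' @export
read_model_table <- function(path, metabolites_path = default_met_path(path)) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#!")]
  get_hdr <- function(key) {
    h <- hdr[grepl(paste0("^#! *", key, ":"), hdr)]
    if (!length(h)) return(NA_character_)
    trimws(sub(paste0("^#! *", key, ":"), "", h[1]))
  }
  body <- lines[!startsWith(lines, "#!")]
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           quote = "", comment.char = "",
                           colClasses = "character")
  need <- c("rxn_id", "equation", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("model table must have columns: ", paste(need, collapse = ", "))
  header_offset <- which(!startsWith(lines, "#!"))[1]
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    eq <- parse_equation(tab$equation[i], line = header_offset + i)
    reaction(tab$rxn_id[i], eq$stoich,
             lb = as.numeric(tab$lb[i]), ub = as.numeric(tab$ub[i]),
             gene_association = if ("genes" %in% names(tab)) tab$genes[i] else "",
             ec = if ("ec" %in% names(tab) && nzchar(tab$ec[i]))
               strsplit(tab$ec[i], ";", fixed = TRUE)[[1]] else character(),
             subsystem = if ("subsystem" %in% names(tab)) tab$subsystem[i] else "")
  })
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  mets <- if (!is.null(metabolites_path) && file.exists(metabolites_path)) {
    mt <- utils::read.table(metabolites_path, sep = "\t", header = TRUE,
                            quote = "", comment.char = "",
                            colClasses = "character")
    lapply(seq_len(nrow(mt)), function(i)
      metabolite(mt$id[i], name = mt$name[i], formula = mt$formula[i],
                 charge = as.numeric(mt$charge[i]),
                 compartment = mt$compartment[i]))
  } else {
    lapply(used, function(id) metabolite(id))
  }
  build_model(mets, rxns, objective_id = get_hdr("objective"),
              name = if (is.na(get_hdr("name"))) "model" else get_hdr("name"),
              version = if (is.na(get_hdr("version"))) "0" else get_hdr("version"))
}

# ---- SBML ------------------------------------------------------------------

gpr_to_fbc_xml <- function(gpr) {
  # parse "a and (b or c)" into nested fbc:and/fbc:or/fbc:geneProductRef
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1
  parse_expr <- function() {
    terms <- list(parse_term()); ops <- character(0)
    while (pos <= length(toks) && tolower(toks[pos]) %in% c("and", "or")) {
      ops <- c(ops, tolower(toks[pos])); pos <<- pos + 1
      terms[[length(terms) + 1]] <- parse_term()
    }
    if (!length(ops)) return(terms[[1]])
    if (length(unique(ops)) > 1)
      stop("mixed and/or without parentheses in GPR: ", gpr)
    list(op = ops[1], args = terms)
  }
  parse_term <- function() {
    if (toks[pos] == "(") {
      pos <<- pos + 1
      e <- parse_expr()
      if (pos > length(toks) || toks[pos] != ")")
        stop("unbalanced parentheses in GPR: ", gpr)
      pos <<- pos + 1
      e
    } else { g <- toks[pos]; pos <<- pos + 1; list(gene = g) }
  }
  parse_expr()
}

gpr_tree_to_string <- function(tree) {
  if (!is.null(tree$gene)) return(tree$gene)
  inner <- vapply(tree$args, gpr_tree_to_string, "")
  paste0("(", paste(inner, collapse = paste0(" ", tree$op, " ")), ")")
}

#' Write a model as SBML Level 3 with the FBC v2 package
#'
#' Elements are emitted in sorted-id order and without timestamps, so two
#' writes of the same model are byte-identical. Stoichiometric coefficients
#' are serialised with 15 significant digits.
#'
#' @param model a `cb_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  L <- character(0)
  push <- function(...) L <<- c(L, paste0(...))
  push("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  push("<sbml xmlns=\"", SBML_NS, "\" xmlns:fbc=\"", FBC_NS,
       "\" level=\"3\" version=\"1\" fbc:required=\"false\">")
  push("  <model id=\"", sbml_escape_id(model$annotations$name),
       "\" name=\"", esc(model$annotations$name), "\" fbc:strict=\"true\">")
  comps <- sort(unique(vapply(model$metabolites, `[[`, "", "compartment")))
  push("    <listOfCompartments>")
  for (cp in comps)
    push("      <compartment id=\"", cp, "\" constant=\"true\"/>")
  push("    </listOfCompartments>")
  push("    <listOfSpecies>")
  for (id in sort(metabolite_ids(model))) {
    m <- model$metabolites[[id]]
    push("      <species id=\"M_", sbml_escape_id(id), "\" name=\"",
         esc(m$name), "\" compartment=\"", m$compartment,
         "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
         " constant=\"false\" fbc:charge=\"", m$charge, "\"",
         if (nzchar(m$formula))
           paste0(" fbc:chemicalFormula=\"", m$formula, "\"") else "",
         "/>")
  }
  push("    </listOfSpecies>")
  bounds <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                          vapply(model$reactions, `[[`, 0, "ub"))))
  bid <- function(v) paste0("cf_bound_", gsub("[^0-9A-Za-z]", "_", num(v)))
  push("    <listOfParameters>")
  for (v in bounds)
    push("      <parameter id=\"", bid(v), "\" value=\"", num(v),
         "\" constant=\"true\"/>")
  push("    </listOfParameters>")
  push("    <listOfReactions>")
  for (id in sort(reaction_ids(model))) {
    r <- model$reactions[[id]]
    push("      <reaction id=\"R_", sbml_escape_id(id), "\" name=\"",
         esc(r$name), "\" reversible=\"",
         tolower(as.character(r$lb < 0)), "\" fast=\"false\"",
         " fbc:lowerFluxBound=\"", bid(r$lb),
         "\" fbc:upperFluxBound=\"", bid(r$ub), "\">")
    if (length(r$ec) || nzchar(r$subsystem)) {
      push("        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">")
      if (length(r$ec)) push("          <p>EC Number: ",
                             paste(r$ec, collapse = ";"), "</p>")
      if (nzchar(r$subsystem)) push("          <p>SUBSYSTEM: ",
                                    esc(r$subsystem), "</p>")
      push("        </body></notes>")
    }
    neg <- r$stoich < 0
    if (any(neg)) {
      push("        <listOfReactants>")
      for (m in sort(names(r$stoich)[neg]))
        push("          <speciesReference species=\"M_", sbml_escape_id(m),
             "\" stoichiometry=\"", num(-r$stoich[[m]]),
             "\" constant=\"true\"/>")
      push("        </listOfReactants>")
    }
    if (any(!neg)) {
      push("        <listOfProducts>")
      for (m in sort(names(r$stoich)[!neg]))
        push("          <speciesReference species=\"M_", sbml_escape_id(m),
             "\" stoichiometry=\"", num(r$stoich[[m]]),
             "\" constant=\"true\"/>")
      push("        </listOfProducts>")
    }
    if (nzchar(r$gene_association)) {
      push("        <fbc:geneProductAssociation>")
      emit <- function(tree, ind) {
        if (!is.null(tree$gene)) {
          push(ind, "<fbc:geneProductRef fbc:geneProduct=\"G_",
               sbml_escape_id(tree$gene), "\"/>")
        } else {
          tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
          push(ind, "<", tag, ">")
          for (a in tree$args) emit(a, paste0(ind, "  "))
          push(ind, "</", tag, ">")
        }
      }
      emit(gpr_to_fbc_xml(r$gene_association), "          ")
      push("        </fbc:geneProductAssociation>")
    }
    push("      </reaction>")
  }
  push("    </listOfReactions>")
  if (!is.na(model$objective_id)) {
    push("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
    push("      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">")
    push("        <fbc:listOfFluxObjectives>")
    push("          <fbc:fluxObjective fbc:reaction=\"R_",
         sbml_escape_id(model$objective_id), "\" fbc:coefficient=\"1\"/>")
    push("        </fbc:listOfFluxObjectives>")
    push("      </fbc:objective>")
    push("    </fbc:listOfObjectives>")
  }
  if (length(model$genes)) {
    push("    <fbc:listOfGeneProducts>")
    for (g in sort(model$genes))
      push("      <fbc:geneProduct fbc:id=\"G_", sbml_escape_id(g),
           "\" fbc:label=\"", esc(g), "\"/>")
    push("    </fbc:listOfGeneProducts>")
  }
  push("  </model>")
  push("</sbml>")
  writeLines(L, path)
  invisible(path)
}

#' Read an SBML model
#'
#' Supports Level 3 with FBC v2 bounds/objective/gene associations, and
#' legacy Level 2 files with kinetic-law `LOWER_BOUND`/`UPPER_BOUND`
#' parameters and `GENE_ASSOCIATION` notes. When both FBC and kinetic-law
#' bounds are present, FBC wins. A model without a recoverable objective
#' loads with the objective unset; simulation refuses until one is set.
#'
#' @param path SBML file.
#' @return a `cb_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop("no <model> element in ", path)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("no species found in ", path)
  sids <- xml2::xml_attr(sp, "id")
  strip_m <- all(startsWith(sids, "M_"))
  clean_s <- function(x) if (strip_m) sub("^M_", "", x) else x
  mets <- lapply(seq_along(sp), function(i) {
    s <- sp[[i]]
    metabolite(clean_s(sids[i]),
               name = attr_or(s, "name", clean_s(sids[i])),
               formula = attr_or(s, "chemicalFormula", ""),
               charge = as.numeric(attr_or(s, "charge", "0")),
               compartment = attr_or(s, "compartment", "c"))
  })
  boundary <- sids[xml2::xml_attr(sp, "boundaryCondition") %in% "true"]
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("no reactions found in ", path)
  rids <- xml2::xml_attr(rx, "id")
  strip_r <- all(startsWith(rids, "R_"))
  clean_r <- function(x) if (strip_r) sub("^R_", "", x) else x
  rxns <- list()
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    sto <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      id <- clean_s(xml2::xml_attr(ref, "species"))
      sto[id] <- (if (id %in% names(sto)) sto[[id]] else 0) -
        as.numeric(attr_or(ref, "stoichiometry", "1"))
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      id <- clean_s(xml2::xml_attr(ref, "species"))
      sto[id] <- (if (id %in% names(sto)) sto[[id]] else 0) +
        as.numeric(attr_or(ref, "stoichiometry", "1"))
    }
    sto <- sto[!(names(sto) %in% clean_s(boundary))]
    if (!length(sto)) next
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbref) && !is.na(ubref)) {
      lb <- parval[[lbref]]; ub <- parval[[ubref]]
    } else {
      kl <- xml2::xml_find_all(
        node, "./kineticLaw//parameter[@id='LOWER_BOUND' or @id='UPPER_BOUND']")
      if (length(kl)) {
        klv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                               xml2::xml_attr(kl, "id"))
        lb <- if ("LOWER_BOUND" %in% names(klv)) klv[["LOWER_BOUND"]] else 0
        ub <- if ("UPPER_BOUND" %in% names(klv)) klv[["UPPER_BOUND"]]
        else UNBOUNDED_FLUX
      } else {
        rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
        lb <- if (rev) -UNBOUNDED_FLUX else 0
        ub <- UNBOUNDED_FLUX
        if (is.na(lbref) != is.na(ubref))
          stop("reaction ", rids[i],
               ": incomplete flux bounds (missing fbc bound attribute)")
      }
    }
    gpa <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (!inherits(gpa, "xml_missing")) fbc_node_to_gpr(gpa) else {
      notes <- xml2::xml_text(xml2::xml_find_first(node, "./notes"))
      ga <- regmatches(notes,
                       regexpr("GENE_ASSOCIATION:[^\n<]*", notes))
      if (length(ga)) trimws(sub("GENE_ASSOCIATION:", "", ga)) else ""
    }
    notes <- xml2::xml_text(xml2::xml_find_first(node, "./notes"))
    ecm <- regmatches(notes, regexpr("EC Number:[^\n<]*", notes))
    ec <- if (length(ecm) && nzchar(trimws(sub("EC Number:", "", ecm))))
      strsplit(trimws(sub("EC Number:", "", ecm)), ";")[[1]] else character()
    ssm <- regmatches(notes, regexpr("SUBSYSTEM:[^\n<]*", notes))
    ss <- if (length(ssm)) trimws(sub("SUBSYSTEM:", "", ssm)) else ""
    rxns[[length(rxns) + 1]] <-
      reaction(clean_r(rids[i]), sto, lb = lb, ub = ub,
               gene_association = if (is.na(gpr)) "" else gpr,
               ec = ec, subsystem = ss,
               name = attr_or(node, "name", clean_r(rids[i])))
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  mets <- Filter(function(m) m$id %in% used, mets)
  fobj <- xml2::xml_find_first(
    doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  objective <- if (!inherits(fobj, "xml_missing"))
    clean_r(xml2::xml_attr(fobj, "reaction")) else NA_character_
  build_model(mets, rxns, objective_id = objective,
              name = attr_or(mod, "name", attr_or(mod, "id", "model")))
}

attr_or <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

fbc_node_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  inner <- vapply(kids, fbc_node_to_gpr, "")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(inner, collapse = op), ")")
}

# ---- media and scenario configs -------------------------------------------

#' Read a medium from a YAML config
#'
#' The file maps exchange ids to `[lb, ub]` pairs, optionally nested under a
#' `medium:` key; the string `unconstrained` stands for the sentinel bound.
#'
#' @param path YAML file.
#' @param sentinel unconstrained-bound magnitude.
#' @return a [medium()].
#' @export
read_medium <- function(path, sentinel = UNBOUNDED_FLUX) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$medium)) y <- y$medium
  conv <- function(v) {
    v <- vapply(v, function(x)
      if (identical(x, "unconstrained")) -sentinel else as.numeric(x), 0)
    if (length(v) == 1) v <- c(v, sentinel)
    v
  }
  do.call(medium, lapply(y, conv))
}

#' Read a simulation scenario from a YAML config
#'
#' Recognised keys: `medium`, `objective`, `bounds` (reaction id to
#' `[lb, ub]` overrides), `q_s`, `substrate`, `fva_fraction`, `transporter`,
#' `me2_direction`, `co2_fraction`, `products` (label to exchange id map).
#'
#' @param path YAML file.
#' @return a `cb_scenario` (see [scenario()]).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario, y[intersect(names(y),
                                names(formals(scenario)))])
}
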