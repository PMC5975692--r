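# Scenario runner: carbon-source growth panels with confusion matrix,
# FVA yield scenarios (transporter mode, malic-enzyme direction, CO2
# availability scans) and by-product ratio ranges.

#' Anaerobic minimal medium for the bundled fixtures
#'
#' Unconstrained CO2, protons, water, phosphate and ammonium; unconstrained
#' cysteine and methionine (auxotrophies); glutamate uptake capped; one
#' carbon source at `-q_s`.
#'
#' @param carbon_exchange exchange id of the sole carbon source (`NULL` for
#'   none).
#' @param q_s substrate uptake rate, mmol/gDCW/h.
#' @param glu_cap glutamate uptake cap (positive number; bound is `-glu_cap`).
#' @param extra named list of additional `c(lb, ub)` entries (e.g. DMSO).
#' @return a [medium()].
#' @export
asuc_minimal_medium <- function(carbon_exchange = "EX_glc__D_e", q_s = 10,
                                glu_cap = 1, extra = list()) {
  U <- UNBOUNDED_FLUX
  m <- list(EX_co2_e = c(-U, U), EX_h_e = c(-U, U), EX_h2o_e = c(-U, U),
            EX_pi_e = c(-U, U), EX_nh4_e = c(-U, U),
            EX_cys__L_e = c(-U, U), EX_met__L_e = c(-U, U),
            EX_glu__L_e = c(-glu_cap, U))
  if (!is.null(carbon_exchange)) m[[carbon_exchange]] <- c(-q_s, 0)
  for (id in names(extra)) m[[id]] <- extra[[id]]
  do.call(medium, m)
}

#' Recompute the glutamate uptake cap from biomass demand
#'
#' Solves growth once with glutamate uptake wide open, measures the uptake
#' the optimum actually uses (glutamate only serves protein synthesis in the
#' fixture networks) and caps the bound at 1.05 times that demand, so
#' glutamate supports growth but cannot act as an extra carbon source.
#'
#' @param model a `cb_model` with a growth objective.
#' @param glu_exchange glutamate exchange id.
#' @param slack multiplicative headroom over the measured demand.
#' @return the model with the recomputed glutamate bound.
#' @export
cap_glutamate <- function(model, glu_exchange = "EX_glu__L_e", slack = 1.05) {
  if (!glu_exchange %in% model$exchanges) return(model)
  probe <- set_reaction_bounds(model, glu_exchange, -UNBOUNDED_FLUX,
                               model$reactions[[glu_exchange]]$ub)
  sol <- tryCatch(pfba(probe), error = function(e) NULL)
  if (is.null(sol) || sol$status != "optimal") return(model)
  demand <- abs(min(sol$fluxes[[glu_exchange]], 0))
  set_reaction_bounds(model, glu_exchange, -slack * demand,
                      model$reactions[[glu_exchange]]$ub)
}

#' Growth call on a sole carbon source
#'
#' Applies the base medium with the source as the only carbon input,
#' recomputes the glutamate cap, maximises biomass and thresholds the
#' growth rate. A source without an exchange reaction in the model is
#' called no-growth with reason `"no transporter/exchange"`.
#'
#' @param model a `cb_model` (objective = biomass).
#' @param carbon_source metabolite id (e.g. `"glc__D_e"`) or exchange id.
#' @param base_medium medium *without* a carbon source, e.g.
#'   `asuc_minimal_medium(NULL)`.
#' @param threshold growth-rate cutoff in 1/h (default 1e-6).
#' @param q_s substrate uptake rate for the source.
#' @return list of class `cb_growth_call`: source, predicted
#'   (`"growth"`/`"no-growth"`), mu_max, threshold, reason.
#' @export
growth_call <- function(model, carbon_source, base_medium = asuc_minimal_medium(NULL),
                        threshold = 1e-6, q_s = 10) {
  ex <- if (carbon_source %in% model$exchanges) carbon_source
  else if (paste0("EX_", carbon_source) %in% model$exchanges)
    paste0("EX_", carbon_source)
  else NA_character_
  mk <- function(predicted, mu, reason = "") {
    structure(list(source = carbon_source, predicted = predicted,
                   mu_max = mu, threshold = threshold, reason = reason),
              class = "cb_growth_call")
  }
  if (is.na(ex)) return(mk("no-growth", 0, "no transporter/exchange"))
  med <- unclass(base_medium)
  med[[ex]] <- c(-q_s, 0)
  m <- apply_medium(model, med)
  m <- cap_glutamate(m)
  sol <- fba(m)
  mu <- if (sol$status == "optimal") sol$objective else 0
  if (sol$status != "optimal") return(mk("no-growth", 0, sol$status))
  mk(if (mu > threshold) "growth" else "no-growth", mu)
}

#' The bundled six-source mini growth panel
#'
#' Carbon sources and observed anaerobic phenotypes used to exercise the
#' growth-call machinery on the fixture network: glucose, sorbitol and
#' xylose grow; glycerol does not (redox imbalance without an external
#' electron acceptor); beta-gentiobiose and D-arabitol grow in vivo but
#' have no transport/catabolic reactions in the network.
#'
#' @return data.frame with columns source and observed (logical).
#' @export
mini_panel <- function() {
  data.frame(
    source = c("glc__D_e", "sbt__D_e", "xyl__D_e", "glyc_e",
               "gentbio_e", "abt__D_e"),
    observed = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Run a growth panel
#'
#' @param model a `cb_model`.
#' @param panel data.frame with `source` and `observed` columns (see
#'   [mini_panel()]).
#' @param base_medium carbon-free base medium.
#' @param threshold growth cutoff in 1/h.
#' @param q_s uptake rate applied to each source.
#' @return list with `calls` (data.frame source, predicted, observed,
#'   mu_max, reason) and `confusion` (a [panel_confusion()] result).
#' @export
run_panel <- function(model, panel = mini_panel(),
                      base_medium = asuc_minimal_medium(NULL),
                      threshold = 1e-6, q_s = 10) {
  calls <- lapply(panel$source, function(s)
    growth_call(model, s, base_medium, threshold, q_s))
  df <- data.frame(
    source = panel$source,
    predicted = vapply(calls, `[[`, "", "predicted") == "growth",
    observed = panel$observed,
    mu_max = vapply(calls, `[[`, 0, "mu_max"),
    reason = vapply(calls, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  list(calls = df,
       confusion = panel_confusion(df$predicted, df$observed, df$source))
}

round_half_up <- function(x) floor(x + 0.5)

#' Growth-phenotype confusion matrix
#'
#' Standard 2x2 tally with growth as the positive class; percentages of the
#' panel size are rounded half-up.
#'
#' @param predicted,observed logical vectors (or `"growth"`/`"no-growth"`
#'   strings) over the same sources.
#' @param sources optional source ids; when given in both inputs' names,
#'   mismatched source sets are an error.
#' @return list of class `cb_confusion`: `tp`, `fp`, `fn`, `tn`, `n` and
#'   `percent` (named, rounded half-up).
#' @export
panel_confusion <- function(predicted, observed, sources = NULL) {
  as_log <- function(x) if (is.logical(x)) x else x == "growth"
  p <- as_log(predicted); o <- as_log(observed)
  if (length(p) != length(o))
    stop("prediction and observation vectors differ in length")
  if (!is.null(names(p)) && !is.null(names(o)) &&
      !setequal(names(p), names(o)))
    stop("mismatched source sets between predictions and observations")
  tp <- sum(p & o); fp <- sum(p & !o); fn <- sum(!p & o); tn <- sum(!p & !o)
  n <- length(p)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 percent = c(tp = round_half_up(100 * tp / n),
                             fp = round_half_up(100 * fp / n),
                             fn = round_half_up(100 * fn / n),
                             tn = round_half_up(100 * tn / n)),
                 sources = sources),
            class = "cb_confusion")
}

#' @export
print.cb_confusion <- function(x, ...) {
  cat("            observed+  observed-\n")
  cat(sprintf("predicted+  TP %2d (%d%%)  FP %2d (%d%%)\n",
              x$tp, x$percent[["tp"]], x$fp, x$percent[["fp"]]))
  cat(sprintf("predicted-  FN %2d (%d%%)  TN %2d (%d%%)\n",
              x$fn, x$percent[["fn"]], x$tn, x$percent[["tn"]]))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A declarative description of one figure-style run: medium, substrate
#' uptake, fraction-of-optimum, bound overrides, transporter mode,
#' malic-enzyme direction and CO2 availability.
#'
#' @param substrate substrate exchange id.
#' @param q_s substrate uptake rate (fixed as the yield basis).
#' @param medium named list of exchange bounds (`NULL`: fixture minimal
#'   medium for the substrate).
#' @param fva_fraction fraction-of-optimum gamma.
#' @param bounds named list of reaction id -> `c(lb, ub)` overrides.
#' @param transporter `NA` to leave the model as built, else `"pts"`,
#'   `"symport"` or `"both"` (closes the other glucose route).
#' @param me2_direction `NA` or `"forward"`/`"reverse"`/`"reversible"`.
#' @param co2_fraction CO2 availability in [0, 1]: 1 = unconstrained uptake,
#'   0 = no uptake, intermediate values scale the reference uptake measured
#'   by pFBA at full availability.
#' @param products named exchange ids reported as yields.
#' @param span_reactions reaction ids whose flux spans are reported.
#' @param objective objective reaction (`NA`: model default).
#' @return list of class `cb_scenario`.
#' @export
scenario <- function(substrate = "EX_glc__D_e", q_s = 10, medium = NULL,
                     fva_fraction = 0.99, bounds = list(),
                     transporter = NA, me2_direction = NA, co2_fraction = 1,
                     products = c(biomass = NA, SA = "EX_succ_e",
                                  AA = "EX_ac_e", FA = "EX_for_e",
                                  EtOH = "EX_etoh_e"),
                     span_reactions = character(),
                     objective = NA) {
  stopifnot(co2_fraction >= 0, co2_fraction <= 1,
            fva_fraction > 0, fva_fraction <= 1)
  structure(list(substrate = substrate, q_s = q_s, medium = medium,
                 fva_fraction = fva_fraction, bounds = bounds,
                 transporter = transporter, me2_direction = me2_direction,
                 co2_fraction = co2_fraction, products = products,
                 span_reactions = span_reactions, objective = objective),
            class = "cb_scenario")
}

# Close the glucose uptake route not selected by the scenario.
apply_transporter_mode <- function(model, mode) {
  if (is.na(mode) || mode == "both") return(model)
  close_ids <- switch(mode,
                      pts = c("GLCt2", "HEX1"),
                      symport = "GLCpts",
                      stop("unknown transporter mode: ", mode))
  for (id in intersect(close_ids, reaction_ids(model)))
    model <- set_reaction_bounds(model, id, 0, 0)
  model
}

apply_me2_direction <- function(model, dir, me2_id = "ME2") {
  if (is.na(dir) || !me2_id %in% reaction_ids(model)) return(model)
  U <- model$sentinel
  b <- switch(dir, forward = c(0, U), reverse = c(-U, 0),
              reversible = c(-U, U), stop("unknown ME2 direction: ", dir))
  set_reaction_bounds(model, me2_id, b[1], b[2])
}

# CO2 availability: 1 = sentinel-unconstrained; 0 = closed; else scale the
# uptake observed by pFBA at full availability.
apply_co2_fraction <- function(model, fraction, co2_exchange = "EX_co2_e") {
  if (!co2_exchange %in% model$exchanges || fraction >= 1) return(model)
  ub <- model$reactions[[co2_exchange]]$ub
  if (fraction == 0) return(set_reaction_bounds(model, co2_exchange, 0, ub))
  open <- set_reaction_bounds(model, co2_exchange, -model$sentinel, ub)
  sol <- pfba(open)
  ref <- abs(min(sol$fluxes[[co2_exchange]], 0))
  set_reaction_bounds(model, co2_exchange, -fraction * ref, ub)
}

# Assemble the constrained model a scenario describes.
scenario_model <- function(model, sc) {
  med <- if (is.null(sc$medium)) {
    unclass(asuc_minimal_medium(sc$substrate, q_s = sc$q_s))
  } else sc$medium
  m <- apply_medium(model, med)
  m <- apply_transporter_mode(m, sc$transporter)
  m <- apply_me2_direction(m, sc$me2_direction)
  for (id in names(sc$bounds))
    m <- set_reaction_bounds(m, id, sc$bounds[[id]][1], sc$bounds[[id]][2])
  if (!is.na(sc$objective)) m <- set_objective(m, sc$objective)
  m <- cap_glutamate(m)
  # fixed yield basis: the substrate uptake equals its bound
  m <- set_reaction_bounds(m, sc$substrate, -sc$q_s, -sc$q_s)
  m <- apply_co2_fraction(m, sc$co2_fraction)
  m
}

#' Run a yield/span scenario
#'
#' Applies the scenario's medium, transporter and malic-enzyme settings,
#' bound overrides and CO2 availability, fixes the substrate uptake as the
#' yield basis, then reports FVA minimum/maximum and pFBA yields for the
#' product set, by-product yield ratios (SA/AA, FA/AA, SA/FA) and flux
#' spans for a named reaction set.
#'
#' @param model a `cb_model` (e.g. [asuc_core_model()]).
#' @param sc a [scenario()].
#' @return list of class `cb_scenario_report`: `status`, `mu_max`, `yields`
#'   (data.frame product, exchange, ymin, ymax, ypfba in mol/mol), `ratios`,
#'   `spans` (FVA table) and `gamma`. An infeasible scenario yields a report
#'   with `status = "infeasible"` rather than an error.
#' @export
run_scenario <- function(model, sc) {
  m <- scenario_model(model, sc)
  base <- fba(m)
  if (base$status != "optimal") {
    return(structure(list(status = base$status, mu_max = NA_real_,
                          yields = NULL, ratios = NULL, spans = NULL,
                          gamma = sc$fva_fraction),
                     class = "cb_scenario_report"))
  }
  prods <- sc$products
  prods[is.na(prods)] <- m$objective_id
  psol <- pfba(m)
  fv <- fva(m, sc$fva_fraction, unique(unname(prods)))
  rownames(fv) <- fv$reaction
  yields <- data.frame(
    product = names(prods), exchange = unname(prods),
    ymin = fv[unname(prods), "vmin"] / sc$q_s,
    ymax = fv[unname(prods), "vmax"] / sc$q_s,
    ypfba = psol$fluxes[unname(prods)] / sc$q_s,
    row.names = NULL, stringsAsFactors = FALSE
  )
  # biomass yield basis is 1/h per mmol/gDCW/h; leave it on that scale
  pairs <- list(c("SA", "AA"), c("FA", "AA"), c("SA", "FA"))
  ratios <- NULL
  if (all(c("SA", "AA", "FA") %in% names(prods))) {
    rows <- lapply(pairs, function(pr) {
      rr <- ratio_range(m, prods[[pr[1]]], prods[[pr[2]]],
                        gamma = sc$fva_fraction, pfba_solution = psol)
      data.frame(ratio = paste(pr[1], pr[2], sep = "/"),
                 rmin = rr[1], rmax = rr[2], stringsAsFactors = FALSE)
    })
    ratios <- do.call(rbind, rows)
  }
  spans <- if (length(sc$span_reactions))
    fva(m, sc$fva_fraction, sc$span_reactions) else NULL
  structure(list(status = "optimal", mu_max = base$objective,
                 yields = yields, ratios = ratios, spans = spans,
                 gamma = sc$fva_fraction),
            class = "cb_scenario_report")
}

#' FVA range of a flux ratio
#'
#' Default mode: the FVA range of the numerator exchange while the
#' denominator is pinned at its pFBA flux (a documented approximation).
#' Exact mode solves the fractional program max/min `v_num / v_den` via the
#' Charnes-Cooper transform (denominator assumed positive).
#'
#' @param model constrained `cb_model` (objective = growth).
#' @param num,den exchange reaction ids (numerator/denominator).
#' @param gamma fraction-of-optimum kept while ranging.
#' @param exact use the Charnes-Cooper fractional LP.
#' @param pfba_solution optional precomputed [pfba()] solution.
#' @return numeric `c(min, max)` of the ratio.
#' @export
ratio_range <- function(model, num, den, gamma = 0.99, exact = FALSE,
                        pfba_solution = NULL) {
  if (!exact) {
    if (is.null(pfba_solution)) pfba_solution <- pfba(model)
    dflux <- pfba_solution$fluxes[[den]]
    if (abs(dflux) < 1e-9) return(c(NA_real_, NA_real_))
    m <- set_reaction_bounds(model, den, dflux, dflux)
    fv <- tryCatch(fva(m, gamma, num), error = function(e) NULL)
    if (is.null(fv)) return(c(NA_real_, NA_real_))
    return(c(fv$vmin / dflux, fv$vmax / dflux))
  }
  # Charnes-Cooper: w = t v, t >= 0; den'w = 1; S w = 0;
  # l t <= w <= u t  as rows with slacks.
  base <- fba(model)
  if (base$status != "optimal") stop("ratio base problem is ", base$status)
  lpd <- model_lp_data(model)
  n <- length(lpd$ids)
  lb <- lpd$lb; ub <- lpd$ub
  iobj <- match(model$objective_id, lpd$ids)
  lb[iobj] <- max(lb[iobj], gamma * base$objective)
  inum <- match(num, lpd$ids); iden <- match(den, lpd$ids)
  m0 <- nrow(lpd$S)
  # columns: w (n), t (1), slacks upper (n), slacks lower (n)
  A <- matrix(0, m0 + 1 + 2 * n, n + 1 + 2 * n)
  A[seq_len(m0), seq_len(n)] <- lpd$S
  A[m0 + 1, iden] <- 1
  for (j in seq_len(n)) {
    A[m0 + 1 + j, j] <- 1; A[m0 + 1 + j, n + 1] <- -ub[j]
    A[m0 + 1 + j, n + 1 + j] <- 1                 # w - u t + s_u = 0
    A[m0 + 1 + n + j, j] <- 1; A[m0 + 1 + n + j, n + 1] <- -lb[j]
    A[m0 + 1 + n + j, n + 1 + n + j] <- -1        # w - l t - s_l = 0
  }
  rhs <- c(rep(0, m0), 1, rep(0, 2 * n))
  big <- 1e6
  lbx <- c(rep(-big, n), 0, rep(0, 2 * n))
  ubx <- rep(big, n + 1 + 2 * n)
  obj <- c(as.numeric(seq_len(n) == inum), rep(0, 1 + 2 * n))
  lo <- solve_lp(obj, A, rhs, lbx, ubx, maximize = FALSE)
  hi <- solve_lp(obj, A, rhs, lbx, ubx, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    return(c(NA_real_, NA_real_))
  c(lo$objective, hi$objective)
}

#' CO2 availability scan
#'
#' Recomputes FVA and pFBA product yields over a grid of CO2 availability
#' fractions (1 = unconstrained uptake, 0 = none).
#'
#' @param model a `cb_model`.
#' @param sc base [scenario()]; its `co2_fraction` is replaced by each grid
#'   value.
#' @param fractions sorted availability fractions in [0, 1].
#' @param products product labels from `sc$products` to report
#'   (default SA, FA, EtOH).
#' @return data.frame fraction, product, ymin, ymax, ypfba.
#' @export
co2_scan <- function(model, sc, fractions = c(0, 0.25, 0.5, 0.75, 1),
                     products = c("SA", "FA", "EtOH")) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  out <- list()
  for (f in fractions) {
    sci <- sc; sci$co2_fraction <- f
    rep <- run_scenario(model, sci)
    if (rep$status != "optimal") next
    y <- rep$yields[rep$yields$product %in% products, ]
    out[[length(out) + 1]] <- data.frame(fraction = f, y,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
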