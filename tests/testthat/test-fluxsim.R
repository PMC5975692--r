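# FBA, pFBA, FVA, theoretical yields and yield arithmetic.

chain_model <- function() {
  build_model(
    list(metabolite("a_e", compartment = "e"), metabolite("a_c"),
         metabolite("b_c"), metabolite("b_e", compartment = "e")),
    list(reaction("EX_a_e", c(a_e = -1), lb = -1, ub = 1000),
         reaction("At", c(a_e = -1, a_c = 1), lb = -1000),
         reaction("AB", c(a_c = -1, b_c = 1), lb = -1000),
         reaction("Bt", c(b_c = -1, b_e = 1), lb = -1000),
         reaction("EX_b_e", c(b_e = -1), lb = 0, ub = 1000)),
    objective_id = "EX_b_e")
}

test_that("fba solves chains, closed media and reports infeasibility", {
  m <- chain_model()
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 1)
  # all uptakes closed -> zero objective
  m0 <- apply_medium(m, medium())
  expect_equal(fba(m0)$objective, 0)
  # forced flux beyond capacity -> infeasible, reported not silent
  mi <- set_reaction_bounds(m, "AB", 5, 10)
  expect_equal(fba(mi)$status, "infeasible")
  # steady state and bounds hold at the optimum
  core <- asuc_core_model()
  s <- fba(core)
  S <- as.matrix(stoich_matrix(core))
  expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
  b <- reaction_bounds(core)
  expect_true(all(s$fluxes >= b$lb - 1e-9 & s$fluxes <= b$ub + 1e-9))
  expect_gt(s$objective, 0)
})

test_that("fba scales linearly with the uptake bound", {
  m <- chain_model()
  for (k in c(0.25, 2, 7)) {
    mk <- set_reaction_bounds(m, "EX_a_e", -k, 1000)
    expect_equal(fba(mk)$objective, k, tolerance = 1e-9)
  }
  core <- asuc_core_model(transporter = "symport")
  y1 <- max_theoretical_yield(core, "EX_succ_e", "EX_glc__D_e",
                              substrate_rate = 1)$y_mol
  y5 <- max_theoretical_yield(core, "EX_succ_e", "EX_glc__D_e",
                              substrate_rate = 5)$y_mol
  expect_equal(y1, y5, tolerance = 1e-9)
})

test_that("pfba keeps the optimum and suppresses futile cycles", {
  # a reversible cycle parallel to the chain gains nothing and is silenced
  m <- build_model(
    list(metabolite("a_e", compartment = "e"), metabolite("a_c"),
         metabolite("b_c"), metabolite("b_e", compartment = "e")),
    list(reaction("EX_a_e", c(a_e = -1), lb = -1),
         reaction("At", c(a_e = -1, a_c = 1)),
         reaction("AB", c(a_c = -1, b_c = 1)),
         reaction("CYC1", c(a_c = -1, b_c = 1), lb = -1000),
         reaction("CYC2", c(b_c = -1, a_c = 1), lb = -1000),
         reaction("Bt", c(b_c = -1, b_e = 1)),
         reaction("EX_b_e", c(b_e = -1))),
    objective_id = "EX_b_e")
  sol <- pfba(m)
  expect_equal(sol$objective, fba(m)$objective, tolerance = 1e-9)
  expect_equal(abs(unname(sol$fluxes[["CYC1"]])) +
                 abs(unname(sol$fluxes[["CYC2"]])), 0, tolerance = 1e-9)
  core <- asuc_core_model()
  expect_equal(pfba(core)$objective, fba(core)$objective, tolerance = 1e-9)
  # parsimony: total |v| no larger than the plain FBA solution's
  expect_lte(pfba(core)$total_abs_flux, fba(core)$total_abs_flux + 1e-6)
})

test_that("fva brackets fluxes at the fraction-of-optimum floor", {
  # single linear pathway at gamma = 0.95: range exactly [0.95 v*, v*]
  m <- chain_model()
  fv <- fva(m, 0.95, c("EX_b_e", "AB"))
  expect_equal(fv$vmin, c(0.95, 0.95), tolerance = 1e-9)
  expect_equal(fv$vmax, c(1, 1), tolerance = 1e-9)
  expect_equal(flux_span(fv), c(EX_b_e = 0.05, AB = 0.05), tolerance = 1e-9)
  # sandwich: vmin <= pFBA flux <= vmax for every reaction, gamma <= 1
  core <- apply_medium(asuc_core_model(), fixture_medium("EX_glc__D_e"))
  p <- pfba(core)
  for (g in c(0.95, 1)) {
    fvc <- fva(core, g)
    expect_true(all(fvc$vmin <= p$fluxes[fvc$reaction] + 1e-6))
    expect_true(all(fvc$vmax >= p$fluxes[fvc$reaction] - 1e-6))
    expect_true(all(fvc$span >= -1e-9))
  }
})

test_that("theoretical yields respect electron and carbon ceilings", {
  # glucose 24 available electrons, succinate 14: max 24/14 mol/mol
  substrates <- c(EX_glc__D_e = 24, EX_sbt__D_e = 26, EX_xyl__D_e = 20)
  for (s in names(substrates)) {
    m <- asuc_core_model(transporter = "both")
    med <- fixture_medium(s, q_s = 1)
    m <- apply_medium(m, med)
    y <- max_theoretical_yield(m, "EX_succ_e", s)
    expect_lte(y$y_mol, substrates[[s]] / 14 + 1e-9)
    # carbon ceiling: product carbon <= substrate carbon + CO2 uptake
    co2_up <- abs(min(y$solution$fluxes[["EX_co2_e"]], 0))
    carbon_in <- capnoflux:::parse_formula(
      m$metabolites[[sub("^EX_", "", s)]]$formula)[["C"]]
    expect_lte(4 * y$y_mol, carbon_in + co2_up + 1e-6)
  }
  # closed substrate errors
  m <- asuc_core_model()
  m <- set_reaction_bounds(m, "EX_glc__D_e", 0, 1000)
  expect_error(max_theoretical_yield(m, "EX_succ_e", "EX_glc__D_e"),
               "closed")
})

test_that("max succinate yield shrinks monotonically with the CO2 bound", {
  caps <- c(1000, 6 / 7, 0.5, 0.25, 0)
  ys <- vapply(caps, function(cap) {
    m <- asuc_core_model(transporter = "symport")
    m <- set_reaction_bounds(m, "EX_co2_e", -cap, 1000)
    max_theoretical_yield(m, "EX_succ_e", "EX_glc__D_e")$y_mol
  }, 0)
  expect_true(all(diff(ys) <= 1e-9))
  expect_equal(ys[1], 12 / 7, tolerance = 1e-9)
  # a CO2 uptake of 6/7 per glucose is exactly what the 12/7 optimum fixes
  expect_equal(ys[2], 12 / 7, tolerance = 1e-9)
  expect_lt(ys[5], 12 / 7)
})

test_that("yield arithmetic converts molar to mass yields", {
  expect_equal(round(mol_to_mass_yield(0.63, 118.09, 180.16), 2), 0.41)
  expect_equal(mol_to_mass_yield(1, 100, 100), 1)
  expect_equal(mol_to_mass_yield(12 / 7, 118.09, 180.16), 1.12,
               tolerance = 5e-3)
  expect_error(mol_to_mass_yield(1, -5, 100), "positive")
  # flux span arithmetic
  expect_equal(flux_span(data.frame(vmin = 0.62, vmax = 0.69)), 0.07,
               tolerance = 1e-12)
  expect_equal(flux_span(data.frame(vmin = 3, vmax = 3)), 0)
})

test_that("random toy networks hit their closed-form optima", {
  set.seed(5)
  for (s in 1:25) {
    t <- random_toy_network(s, n_branches = sample(0:6, 1))
    expect_equal(fba(t$model)$objective, t$optimum, tolerance = 1e-9)
  }
  t0 <- random_toy_network(99, n_branches = 0)
  expect_equal(fba(t0$model)$objective, t0$uptake, tolerance = 1e-9)
})
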