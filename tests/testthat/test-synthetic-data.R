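# Fixture generators: determinism, consistency, built-in physiology.

test_that("generators are deterministic for fixed options and seeds", {
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(asuc_core_model("pts", "reverse", hydrogenase = TRUE), p1)
  write_sbml(asuc_core_model("pts", "reverse", hydrogenase = TRUE), p2)
  expect_identical(readLines(p1), readLines(p2))
  t1 <- random_toy_network(7, 3); t2 <- random_toy_network(7, 3)
  expect_identical(t1$yields, t2$yields)
  expect_identical(synth_hit_table(9), synth_hit_table(9))
  # the generator restores the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(synth_hit_table(1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("every generated model is stoichiometrically consistent", {
  check <- function(model, exclude = c("BIOMASS")) {
    S <- as.matrix(stoich_matrix(model))
    internal <- setdiff(reaction_ids(model), c(model$exchanges, exclude))
    Si <- S[, internal, drop = FALSE]
    # a strictly positive metabolite mass vector m with m' S_internal = 0
    r <- capnoflux:::solve_lp(rep(0, nrow(Si)), t(Si), rep(0, ncol(Si)),
                              lb = rep(1, nrow(Si)), ub = rep(1e4, nrow(Si)))
    r$status
  }
  expect_equal(check(asuc_core_model()), "optimal")
  expect_equal(check(asuc_core_model("symport", "reverse",
                                     hydrogenase = TRUE, dmso = TRUE,
                                     bicarbonate = TRUE)), "optimal")
  expect_equal(check(oxtca_core_model(), exclude = character(0)), "optimal")
  set.seed(3)
  for (s in 1:5)
    expect_equal(check(random_toy_network(s, 4)$model,
                       exclude = character(0)), "optimal")
})

test_that("ASUC-CORE grows anaerobically and ferments to succinate", {
  core <- asuc_core_model()
  sol <- pfba(core)
  expect_gt(sol$objective, 0.05)
  expect_gt(sol$fluxes[["EX_succ_e"]], 0.1)      # mixed-acid with C4 flux
  expect_gt(sol$fluxes[["EX_ac_e"]], 0)
  expect_lt(sol$fluxes[["EX_co2_e"]], 0)         # net CO2 fixation
  # succinyl-CoA ligase is structurally absent: no C4 flux from succinyl-CoA
  expect_false("SUCOAS" %in% reaction_ids(core))
})

test_that("transporter options gate the glucose routes", {
  pts <- asuc_core_model("pts")
  expect_true("GLCpts" %in% reaction_ids(pts))
  expect_false("GLCt2" %in% reaction_ids(pts))
  sym <- asuc_core_model("symport")
  expect_false("GLCpts" %in% reaction_ids(sym))
  expect_true(all(c("GLCt2", "HEX1") %in% reaction_ids(sym)))
  both <- asuc_core_model("both")
  expect_true(all(c("GLCpts", "GLCt2") %in% reaction_ids(both)))
  # PEP drain: PTS-only theoretical SA ceiling below symport's (ME2 forward)
  y_pts <- max_theoretical_yield(asuc_core_model("pts", "forward"),
                                 "EX_succ_e", "EX_glc__D_e")$y_mol
  y_sym <- max_theoretical_yield(asuc_core_model("symport", "forward"),
                                 "EX_succ_e", "EX_glc__D_e")$y_mol
  expect_lt(y_pts, y_sym)
})

test_that("hydrogenase option adds the H2-driven reductive ceiling", {
  m <- asuc_core_model(hydrogenase = TRUE)
  expect_true(all(c("HYD", "H2t", "EX_h2_e") %in% reaction_ids(m)))
  m <- set_reaction_bounds(m, "EX_h2_e", -1000, 1000)
  y <- max_theoretical_yield(m, "EX_succ_e", "EX_glc__D_e")
  expect_equal(y$y_mol, 2, tolerance = 1e-9)
  expect_false("HYD" %in% reaction_ids(asuc_core_model()))
})

test_that("carbonic anhydrase toggle changes no yields", {
  for (tr in c("pts", "symport")) {
    y0 <- max_theoretical_yield(asuc_core_model(tr),
                                "EX_succ_e", "EX_glc__D_e")$y_mol
    y1 <- max_theoretical_yield(asuc_core_model(tr, bicarbonate = TRUE),
                                "EX_succ_e", "EX_glc__D_e")$y_mol
    expect_equal(y0, y1, tolerance = 1e-9)
  }
  g0 <- fba(asuc_core_model())$objective
  g1 <- fba(asuc_core_model(bicarbonate = TRUE))$objective
  expect_equal(g0, g1, tolerance = 1e-9)
})

test_that("OXTCA-CORE is the oxidative template it claims to be", {
  m <- oxtca_core_model()
  expect_false(any(c("FRDmq", "PPCK") %in% reaction_ids(m)))
  expect_true(all(c("PDH", "CS", "ICDHx", "AKGD", "SUCOAS", "PPC", "NOX")
                  %in% reaction_ids(m)))
  # without anaplerosis, no oxaloacetate regeneration: succinate impossible
  m0 <- set_reaction_bounds(m, "PPC", 0, 0)
  y0 <- max_theoretical_yield(m0, "EX_succ_e", "EX_glc__D_e",
                              biomass_id = NA)
  expect_equal(y0$y_mol, 0, tolerance = 1e-9)
})

test_that("planted hit tables honour their knobs", {
  h <- synth_hit_table(5, true_ec = "2.7.1.11", n_hits = 30,
                       truth_fraction = 0.5, taxonomy_bias = FALSE)
  expect_equal(nrow(h), 30)
  expect_equal(sum(h$ec == "2.7.1.11"), 15)
  expect_true(all(diff(h$score) < 0))  # strictly decaying down the ranking
  # truth_fraction 1: unanimity, score exactly 1
  h1 <- synth_hit_table(6, truth_fraction = 1)
  s1 <- functional_score(h1)
  expect_equal(s1$score, 1)
  # equal scores, no bias, half-half: an exact tie
  h2 <- hit_df(c(rep("1.1.1.37", 5), rep("1.1.1.1", 5)))
  expect_true(attr(functional_score(h2), "tie"))
})

test_that("fixture manifests track model size and options", {
  m <- asuc_core_model()
  mf <- fixture_manifest(m, list(transporter = "both", me2 = "reversible"))
  expect_equal(mf$id, "ASUC-CORE")
  expect_equal(mf$n_reactions, length(m$reactions))
  expect_equal(mf$n_metabolites, length(m$metabolites))
  expect_gte(mf$n_exchanges, 11)
  expect_equal(mf$options$transporter, "both")
})
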