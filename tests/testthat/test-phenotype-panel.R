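# Growth panels, confusion matrices, yield scenarios and CO2 scans.

test_that("growth calls: fixture sources, missing transporters, threshold", {
  core <- asuc_core_model()
  g <- growth_call(core, "glc__D_e")
  expect_equal(g$predicted, "growth")
  expect_gt(g$mu_max, 0.1)
  miss <- growth_call(core, "glyc_e")
  expect_equal(miss$predicted, "no-growth")
  expect_equal(miss$reason, "no transporter/exchange")
  # an absurd threshold flips the call without touching the rate
  hi <- growth_call(core, "glc__D_e", threshold = 10)
  expect_equal(hi$predicted, "no-growth")
  expect_equal(hi$mu_max, g$mu_max, tolerance = 1e-9)
})

test_that("glutamate cap tracks biomass demand, not carbon appetite", {
  core <- apply_medium(asuc_core_model(), fixture_medium("EX_glc__D_e"))
  capped <- cap_glutamate(core)
  lb <- capped$reactions$EX_glu__L_e$lb
  expect_lt(lb, 0)
  sol <- pfba(capped)
  # the cap leaves just 5% headroom over what growth actually uses
  expect_gte(abs(lb), abs(sol$fluxes[["EX_glu__L_e"]]) - 1e-6)
  expect_lte(abs(lb), abs(sol$fluxes[["EX_glu__L_e"]]) * 1.06)
  # glutamate carbon cannot boost growth: opening it wide changes nothing
  open <- set_reaction_bounds(core, "EX_glu__L_e", -1000, 1000)
  expect_equal(fba(open)$objective, fba(capped)$objective, tolerance = 1e-6)
})

test_that("the mini panel exercises TP, TN and FN cells as observed", {
  rp <- run_panel(asuc_core_model())
  cf <- rp$confusion
  expect_equal(c(cf$tp, cf$fp, cf$fn, cf$tn), c(3, 0, 2, 1))
  expect_equal(sum(cf$tp, cf$fp, cf$fn, cf$tn), nrow(mini_panel()))
  expect_true(all(rp$calls$predicted[rp$calls$source %in%
                                       c("glc__D_e", "sbt__D_e", "xyl__D_e")]))
})

test_that("confusion matrix arithmetic matches the published panel", {
  # 22 sources: 19 correct growth, 1 correct no-growth, 2 missed growth
  obs <- c(rep(TRUE, 21), FALSE)
  pred <- c(rep(TRUE, 19), FALSE, FALSE, FALSE)
  cf <- panel_confusion(pred, obs)
  expect_equal(c(cf$tp, cf$fp, cf$fn, cf$tn), c(19, 0, 2, 1))
  expect_equal(unname(cf$percent), c(86, 0, 9, 5))
  expect_equal(sum(cf$percent), 100)
  # identical vectors: no errors
  cf2 <- panel_confusion(obs, obs)
  expect_equal(cf2$fp + cf2$fn, 0)
  # inverting predictions swaps TP<->FN and TN<->FP
  cf3 <- panel_confusion(!pred, obs)
  expect_equal(c(cf3$tp, cf3$fn), c(cf$fn, cf$tp))
  expect_equal(c(cf3$fp, cf3$tn), c(cf$tn, cf$fp))
  expect_error(panel_confusion(pred[1:5], obs), "length")
  expect_error(panel_confusion(stats::setNames(c(TRUE, FALSE), c("a", "b")),
                               stats::setNames(c(TRUE, FALSE), c("a", "c"))),
               "mismatched")
})

test_that("PTS-only transport lowers succinate yields versus PTS+symport", {
  # theoretical route, malic enzyme held forward-only (PEP drain effect)
  y_pts <- max_theoretical_yield(asuc_core_model("pts", me2 = "forward"),
                                 "EX_succ_e", "EX_glc__D_e")$y_mol
  y_sym <- max_theoretical_yield(asuc_core_model("symport", me2 = "forward"),
                                 "EX_succ_e", "EX_glc__D_e")$y_mol
  expect_lt(y_pts, y_sym)
  # growth-coupled FVA max at 99% of optimum
  up <- function(tr) {
    m <- apply_medium(asuc_core_model(tr), fixture_medium("EX_glc__D_e"))
    m <- set_reaction_bounds(m, "EX_glc__D_e", -10, -10)
    fva(m, 0.99, "EX_succ_e")
  }
  expect_lte(up("pts")$vmax, up("both")$vmax + 1e-6)
})

test_that("reverse malic enzyme raises the succinate FVA ceiling", {
  sa_range <- function(me2) {
    m <- apply_medium(asuc_core_model("pts", me2 = me2),
                      fixture_medium("EX_glc__D_e"))
    m <- set_reaction_bounds(m, "EX_glc__D_e", -10, -10)
    fva(m, 0.99, "EX_succ_e")
  }
  fwd <- sa_range("forward"); rev <- sa_range("reverse")
  bi <- sa_range("reversible")
  expect_gte(rev$vmax, fwd$vmax - 1e-6)
  expect_gte(bi$vmax, fwd$vmax - 1e-6)
  expect_gt(rev$vmax, fwd$vmax)   # strictly better on the fixture
})

test_that("more reduced substrate: sorbitol beats glucose on SA mass yield", {
  run <- function(sub, mass) {
    m <- apply_medium(asuc_core_model("pts"), fixture_medium(sub))
    m <- set_reaction_bounds(m, sub, -10, -10)
    fv <- fva(m, 0.99, "EX_succ_e")
    mol_to_mass_yield(fv$vmax / 10, 118.09, mass)
  }
  expect_gte(run("EX_sbt__D_e", 182.17), run("EX_glc__D_e", 180.16) - 1e-6)
})

test_that("scenarios report yields, ratios and spans; infeasible is graceful", {
  core <- asuc_core_model()
  rep <- run_scenario(core, scenario(q_s = 10, fva_fraction = 0.99,
                                     span_reactions = c("PPCK", "PYK", "PGI",
                                                        "PFK", "ENO")))
  expect_equal(rep$status, "optimal")
  expect_gt(rep$mu_max, 0)
  expect_setequal(rep$yields$product, c("biomass", "SA", "AA", "FA", "EtOH"))
  y <- rep$yields
  expect_true(all(y$ymin <= y$ypfba + 1e-6 & y$ypfba <= y$ymax + 1e-6))
  expect_setequal(rep$ratios$ratio, c("SA/AA", "FA/AA", "SA/FA"))
  expect_true(all(rep$spans$span >= -1e-9))
  # PEP-node flexibility dwarfs the Embden-Meyerhof trunk's
  sp <- stats::setNames(rep$spans$span, rep$spans$reaction)
  expect_gt(sp[["PPCK"]], sp[["PGI"]])
  expect_gt(sp[["PYK"]], sp[["ENO"]])
  # infeasible scenario: structured report, not a crash
  bad <- scenario(bounds = list(ATPM = c(500, 1000)))
  rep2 <- run_scenario(core, bad)
  expect_equal(rep2$status, "infeasible")
})

test_that("zero-flux constraint on a reaction is honoured in scenarios", {
  # the fixture has no succinyl-CoA ligase: the constraint is structural,
  # emulated here by pinning an active reaction instead
  core <- asuc_core_model()
  expect_false("SUCOAS" %in% reaction_ids(core))
  rep <- run_scenario(core, scenario(bounds = list(OAADC = c(0, 0))))
  expect_equal(rep$status, "optimal")
})

test_that("CO2 scan: endpoints, pFBA trend and C3 compensation", {
  core <- asuc_core_model()
  sc <- scenario(q_s = 10, fva_fraction = 0.99)
  scan <- co2_scan(core, sc, fractions = c(0, 0.5, 1))
  sa <- scan[scan$product == "SA", ]
  # fraction 1 reproduces the uncapped scenario exactly
  full <- run_scenario(core, sc)
  expect_equal(sa$ymax[sa$fraction == 1],
               full$yields$ymax[full$yields$product == "SA"],
               tolerance = 1e-9)
  # pFBA succinate yield falls as CO2 availability falls
  expect_true(all(diff(sa$ypfba[order(sa$fraction)]) >= -1e-9))
  # max SA strictly lower with no CO2 than unconstrained
  expect_lt(sa$ymax[sa$fraction == 0], sa$ymax[sa$fraction == 1])
  # carbon shifts toward C3 products: formate+ethanol pFBA yields rise
  c3 <- scan[scan$product %in% c("FA", "EtOH"), ]
  c3sum <- tapply(c3$ypfba, c3$fraction, sum)
  expect_gte(c3sum[["0"]], c3sum[["1"]] - 1e-9)
  # availability-fraction invariant: 0 closes uptake entirely
  m0 <- capnoflux:::apply_co2_fraction(core, 0)
  expect_equal(m0$reactions$EX_co2_e$lb, 0)
})

test_that("DMSO respiration restores glycerol growth", {
  md <- asuc_core_model(dmso = TRUE)
  plain <- growth_call(md, "glyc_e", asuc_minimal_medium(NULL))
  expect_equal(plain$predicted, "no-growth")  # zero net ATP without acceptor
  with_dmso <- growth_call(
    md, "glyc_e",
    asuc_minimal_medium(NULL, extra = list(EX_dmso_e = c(-1000, 1000),
                                           EX_dms_e = c(0, 1000))))
  expect_equal(with_dmso$predicted, "growth")
  expect_gt(with_dmso$mu_max, 0.05)
})

test_that("exact ratio ranges agree with direct enumeration on a toy", {
  # two outputs share one substrate: ratio p1/p2 spans [lb-driven] range
  m <- build_model(
    list(metabolite("s_e", compartment = "e"), metabolite("s_c"),
         metabolite("p_c"), metabolite("p_e", compartment = "e"),
         metabolite("q_c"), metabolite("q_e", compartment = "e")),
    list(reaction("EX_s_e", c(s_e = -1), lb = -1, ub = -1),
         reaction("St", c(s_e = -1, s_c = 1)),
         reaction("RP", c(s_c = -1, p_c = 1)),
         reaction("RQ", c(s_c = -1, q_c = 1), lb = 0.2),
         reaction("Pt", c(p_c = -1, p_e = 1)),
         reaction("Qt", c(q_c = -1, q_e = 1)),
         reaction("EX_p_e", c(p_e = -1)),
         reaction("EX_q_e", c(q_e = -1))),
    objective_id = "EX_p_e")
  # q >= 0.2 forced, p = 1 - q: ratio p/q ranges over [0, 0.8/0.2] = [0, 4]
  rr <- ratio_range(m, "EX_p_e", "EX_q_e", gamma = 1e-9, exact = TRUE)
  expect_equal(rr[1], 0, tolerance = 1e-6)
  expect_equal(rr[2], 4, tolerance = 1e-6)
})
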