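# Balance checking, proton/water repair, dead ends, blocked reactions.

balance_fixture <- function(rxns) {
  mets <- list(
    metabolite("glc_c", formula = "C6H12O6", charge = 0),
    metabolite("g6p_c", formula = "C6H11O9P", charge = -2),
    metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4),
    metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3),
    metabolite("h_c", formula = "H", charge = 1),
    metabolite("h2o_c", formula = "H2O", charge = 0),
    metabolite("a_c", formula = "C2H4O2", charge = 0),
    metabolite("b_c", formula = "C2H4O2", charge = 0),
    metabolite("x_c", formula = "", charge = 0)
  )
  build_model(mets, rxns, objective_id = NA_character_)
}

test_that("element_balance reproduces hand-computed residuals", {
  # glucose + ATP -> G6P + ADP omits the released proton: H residual -1,
  # charge residual -1; repair: one proton added to the products
  m <- balance_fixture(list(
    reaction("HEX_BAD", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1)),
    reaction("IDENT", c(a_c = -1, b_c = 1)),
    reaction("NOFML", c(a_c = -1, x_c = 1))
  ))
  b <- element_balance(m, "HEX_BAD")
  expect_equal(b$status, "imbalanced")
  expect_equal(b$element_residual[["H"]], -1)
  expect_equal(b$charge_residual, -1)
  fix <- b$suggested_fix
  expect_length(fix, 1)
  expect_equal(fix[[1]]$metabolite, "h_c")
  expect_equal(fix[[1]]$coefficient, 1)   # one proton joins the products
  expect_equal(element_balance(m, "IDENT")$status, "balanced")
  bn <- element_balance(m, "NOFML")
  expect_equal(bn$status, "unverifiable")
  expect_equal(bn$missing, "x_c")
})

test_that("suggest_balancing solves the proton/water system or flags", {
  rep0 <- function(el, ch) structure(
    list(rxn_id = "R", status = "imbalanced", element_residual = el,
         charge_residual = ch, compartment = "c"),
    class = "cb_balance_report")
  # H -2, O -1 -> one water to the products
  f <- suggest_balancing(rep0(c(H = -2, O = -1), 0))
  expect_length(f, 1)
  expect_equal(f[[1]]$metabolite, "h2o_c")
  expect_equal(f[[1]]$coefficient, 1)
  # H -1, charge -1 -> one proton to the products
  f2 <- suggest_balancing(rep0(c(H = -1), -1))
  expect_equal(f2[[1]]$metabolite, "h_c")
  expect_equal(f2[[1]]$coefficient, 1)
  # carbon residual: structural imbalance, no fix
  f3 <- suggest_balancing(rep0(c(C = -1), 0))
  expect_length(f3, 0)
  expect_true(attr(f3, "structural"))
  # inconsistent H/O/charge system: empty but not structural
  f4 <- suggest_balancing(rep0(c(H = -1), 0.5))
  expect_length(f4, 0)
  expect_false(attr(f4, "structural"))
})

test_that("applying the suggested fix re-balances (random perturbations)", {
  core <- asuc_core_model()
  candidates <- setdiff(reaction_ids(core),
                        c(core$exchanges, "BIOMASS", "PROT_SYN", "GLYC_SYN"))
  set.seed(31)
  for (i in 1:40) {
    id <- sample(candidates, 1)
    r <- core$reactions[[id]]
    comp <- capnoflux:::majority_compartment(core, r)
    h <- paste0("h_", comp); w <- paste0("h2o_", comp)
    dh <- sample(-2:2, 1); dw <- sample(-2:2, 1)
    if (dh == 0 && dw == 0) next
    st <- r$stoich
    st[h] <- (if (h %in% names(st)) st[[h]] else 0) + dh
    st[w] <- (if (w %in% names(st)) st[[w]] else 0) + dw
    st <- st[st != 0]
    if (!length(st)) next
    m <- core
    m$reactions[[id]]$stoich <- st
    b <- element_balance(m, id)
    if (b$status == "balanced") next  # perturbation cancelled out
    expect_equal(b$status, "imbalanced")
    fix <- b$suggested_fix
    expect_gt(length(fix), 0)
    st2 <- st
    for (f in fix) {
      st2[f$metabolite] <- (if (f$metabolite %in% names(st2))
        st2[[f$metabolite]] else 0) + f$coefficient
    }
    m$reactions[[id]]$stoich <- st2[st2 != 0]
    expect_equal(element_balance(m, id)$status, "balanced")
  }
})

test_that("dead-end detection matches the dense-matrix oracle", {
  # hand case: chain with exchange on A only -> C is only-produced
  m <- build_model(
    list(metabolite("a_c"), metabolite("b_c"), metabolite("c_c")),
    list(reaction("EX_a_c", c(a_c = -1), lb = -10),
         reaction("R1", c(a_c = -1, b_c = 1)),
         reaction("R2", c(b_c = -1, c_c = 1))),
    objective_id = NA_character_)
  de <- find_dead_ends(m)
  expect_equal(de$metabolite, "c_c")
  expect_equal(de$mode, "only-produced")
  # reversible A<->B with exchange on A: no dead end
  m2 <- build_model(
    list(metabolite("a_c"), metabolite("b_c")),
    list(reaction("EX_a_c", c(a_c = -1), lb = -10),
         reaction("R1", c(a_c = -1, b_c = 1), lb = -1000)),
    objective_id = NA_character_)
  expect_equal(nrow(find_dead_ends(m2)), 0)
  # randomised agreement with the oracle
  set.seed(17)
  for (i in 1:40) {
    rm <- random_qc_network(sample(5:15, 1), sample(4:14, 1))
    expect_setequal(find_dead_ends(rm)$metabolite, dead_end_oracle(rm))
  }
})

test_that("ASUC-CORE passes curation: no dead ends, no imbalances", {
  m <- asuc_core_model(hydrogenase = TRUE, dmso = TRUE, bicarbonate = TRUE)
  expect_equal(nrow(find_dead_ends(m)), 0)
  bt <- balance_table(m)
  expect_equal(sum(bt$status == "imbalanced"), 0)
  expect_equal(sum(bt$status == "unverifiable"), 0)
  expect_equal(nrow(find_dead_ends(oxtca_core_model())), 0)
  bo <- balance_table(oxtca_core_model())
  expect_equal(sum(bo$status == "imbalanced"), 0)
})

test_that("blocked reactions: downstream of gaps, hydrogenase off, monotone", {
  # reaction downstream of a dead end is blocked
  m <- build_model(
    list(metabolite("a_c"), metabolite("b_c"), metabolite("c_c")),
    list(reaction("EX_a_c", c(a_c = -1), lb = -10),
         reaction("R1", c(a_c = -1, b_c = 1)),
         reaction("R2", c(b_c = -1, c_c = 1))),
    objective_id = NA_character_)
  expect_true(all(c("R1", "R2") %in% find_blocked_reactions(m)))
  # coupled pathway with no exchange at all: every member is blocked
  # (a closed a->b->a loop is excluded: plain FVA admits circulating flux,
  # and loop-free variability analysis is out of scope)
  m2 <- build_model(
    list(metabolite("a_c"), metabolite("b_c"), metabolite("c_c")),
    list(reaction("R1", c(a_c = -1, b_c = 1)),
         reaction("R2", c(b_c = -1, c_c = 1))),
    objective_id = NA_character_)
  expect_setequal(find_blocked_reactions(m2), c("R1", "R2"))
  # hydrogenase with H2 uptake closed: HYD and its exchange are blocked
  mh <- asuc_core_model(hydrogenase = TRUE)
  bl <- find_blocked_reactions(mh)
  expect_true(all(c("HYD", "EX_h2_e") %in% bl))
  # opening H2 unblocks: the blocked set shrinks as the medium is relaxed
  mh_open <- set_reaction_bounds(mh, "EX_h2_e", -1000, 1000)
  bl_open <- find_blocked_reactions(mh_open)
  expect_true(all(bl_open %in% bl))
  expect_false("HYD" %in% bl_open)
})
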