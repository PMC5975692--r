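# Independent oracles used across the suite. These deliberately avoid the
# package's solver/QC code paths.

# Exhaustive basic-solution enumeration for max c'x, A x = b, l <= x <= u.
# Returns list(feasible, optimum). Valid for small n (<= 8 columns).
lp_vertex_oracle <- function(cc, A, b, lb, ub) {
  n <- ncol(A); m <- nrow(A)
  best <- -Inf; feas <- FALSE
  combs <- utils::combn(n, min(m, n), simplify = FALSE)
  for (Bi in combs) {
    Nb <- setdiff(seq_len(n), Bi)
    Bm <- A[, Bi, drop = FALSE]
    if (abs(det(Bm)) < 1e-9) next
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), length(Nb))))
    if (!length(Nb)) grid <- matrix(0, 1, 0)
    for (g in seq_len(nrow(grid))) {
      xN <- if (length(Nb)) ifelse(grid[g, ] == 1, lb[Nb], ub[Nb]) else numeric(0)
      rhs <- b - (if (length(Nb)) A[, Nb, drop = FALSE] %*% xN else rep(0, m))
      xB <- tryCatch(solve(Bm, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[Bi] <- xB
      if (length(Nb)) x[Nb] <- xN
      if (all(x >= lb - 1e-9 & x <= ub + 1e-9)) {
        feas <- TRUE
        best <- max(best, sum(cc * x))
      }
    }
  }
  list(feasible = feas, optimum = best)
}

random_small_lp <- function() {
  n <- sample(2:8, 1)
  m <- sample(1:(n - 1), 1)
  list(A = matrix(sample(-2:2, m * n, TRUE), m, n),
       b = round(stats::runif(m, -1, 1), 2),
       lb = round(stats::runif(n, -3, 0), 2),
       ub = round(stats::runif(n, 0.1, 3), 2),
       cc = round(stats::runif(n, -1, 1), 3))
}

# Dead-end classification straight off the dense stoichiometric matrix.
dead_end_oracle <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  bounds <- reaction_bounds(model)
  is_ex <- bounds$id %in% model$exchanges
  fwd <- is_ex | bounds$ub > 1e-12
  bwd <- is_ex | bounds$lb < -1e-12
  out <- character(0)
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    prod <- any((row > 0 & fwd) | (row < 0 & bwd))
    cons <- any((row < 0 & fwd) | (row > 0 & bwd))
    if (!(prod && cons)) out <- c(out, rownames(S)[i])
  }
  out
}

# Random small network for dead-end cross-checks; reactions drawn over a
# metabolite pool with random reversibility and a random exchange subset.
random_qc_network <- function(n_mets = 8, n_rxns = 10) {
  mets <- paste0("m", seq_len(n_mets), "_c")
  rxns <- list()
  for (j in seq_len(n_rxns)) {
    k <- sample(2:3, 1)
    ids <- sample(mets, k)
    coef <- c(-1, rep(1, k - 1))
    rev <- stats::runif(1) < 0.4
    rxns[[j]] <- reaction(paste0("r", j), stats::setNames(coef, ids),
                          lb = if (rev) -1000 else 0, ub = 1000)
  }
  for (id in sample(mets, sample(1:3, 1))) {
    rxns[[length(rxns) + 1]] <- reaction(paste0("EX_", id),
                                         stats::setNames(-1, id),
                                         lb = -1000, ub = 1000)
  }
  build_model(lapply(mets, metabolite), rxns, objective_id = NA_character_)
}

# Carbon content vector of a model's metabolites (NA when formula missing).
carbon_vector <- function(model) {
  vapply(model$metabolites, function(m) {
    comp <- parse_formula(m$formula)
    if (!length(comp)) return(NA_real_)
    if ("C" %in% names(comp)) comp[["C"]] else 0
  }, 0)
}

# Anaerobic fixture medium for a sole substrate at a fixed uptake.
fixture_medium <- function(substrate, q_s = 10, ...) {
  asuc_minimal_medium(substrate, q_s = q_s, ...)
}
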