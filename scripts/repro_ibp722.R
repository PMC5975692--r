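#!/usr/bin/env Rscript

# Opt-in reproduction runs against the deposited genome-scale model of
# Actinobacillus succinogenes 130Z (iBP722, BioModels MODEL1804130001).
# The SBML is NOT bundled; download it first, e.g.
#
#   curl -L -o ibp722.xml \
#     "https://www.ebi.ac.uk/biomodels/model/download/MODEL1804130001?filename=MODEL1804130001_url.xml"
#
# then run
#
#   Rscript scripts/repro_ibp722.R --model ibp722.xml [--out results/ibp722]
#
# What is recomputed (printed values from the original study in brackets):
#   * model statistics                 [1072 reactions, 722 genes, 713 metabolites]
#   * anaerobic glucose growth and succinate FVA yields at 99% of max growth
#     under PTS-only vs PTS+symport glucose uptake  [0.63-0.67 vs 0.82-0.96 mol/mol]
#   * alcohol-dehydrogenase FVA yields on sorbitol  [0.62-0.69 mol/mol]
#   * max-SA-yield change when halving CO2 uptake   [~20% decrease]
# Growth-panel reproduction additionally needs the supplementary carbon-source
# list and constraint table, supplied as a panel TSV via --panel.
#
# Reaction/exchange identifiers in the deposited file may differ from the
# BiGG-style ids used below; override them via the options at the top.

suppressPackageStartupMessages(library(capnoflux))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
model_path <- get_arg("--model")
if (is.null(model_path)) stop("usage: repro_ibp722.R --model <sbml> ",
                              "[--panel <tsv>] [--out <dir>]")
out_dir <- get_arg("--out", "results/ibp722")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ids <- list(glc = get_arg("--ex-glc", "EX_glc__D_e"),
            sorb = get_arg("--ex-sorb", "EX_sbt__D_e"),
            succ = get_arg("--ex-succ", "EX_succ_e"),
            co2 = get_arg("--ex-co2", "EX_co2_e"),
            alcd = get_arg("--alcd", "ALCD2x"),
            pts = get_arg("--pts", "GLCpts"),
            symport = get_arg("--symport", "GLCt2"))

message("reading ", model_path)
m <- read_sbml(model_path)
s <- model_stats(m)
print(s)

res <- list(stats = unclass(s))

try_run <- function(label, expr) {
  out <- tryCatch(expr, error = function(e) {
    message(label, ": skipped (", conditionMessage(e), ")")
    NULL
  })
  if (!is.null(out)) res[[label]] <<- out
  out
}

try_run("sa_fva_pts_vs_both", {
  stopifnot(all(c(ids$glc, ids$succ) %in% m$exchanges))
  run <- function(close_symport) {
    mm <- m
    if (close_symport && ids$symport %in% reaction_ids(mm))
      mm <- set_reaction_bounds(mm, ids$symport, 0, 0)
    mm <- set_reaction_bounds(mm, ids$glc, -10, -10)
    fv <- fva(mm, 0.99, ids$succ)
    c(min = fv$vmin / 10, max = fv$vmax / 10)
  }
  list(pts_only = run(TRUE), pts_symport = run(FALSE))
})

try_run("alcd_fva_sorbitol", {
  stopifnot(ids$sorb %in% m$exchanges, ids$alcd %in% reaction_ids(m))
  mm <- apply_medium(m, stats::setNames(list(c(-10, 0)), ids$sorb))
  mm <- set_reaction_bounds(mm, ids$sorb, -10, -10)
  fv <- fva(mm, 0.99, ids$alcd)
  c(min = fv$vmin / 10, max = fv$vmax / 10)
})

try_run("co2_halving_sa_drop", {
  mm <- set_reaction_bounds(m, ids$glc, -10, -10)
  ref <- pfba(mm)
  up <- abs(min(ref$fluxes[[ids$co2]], 0))
  y_full <- fva(mm, 0.99, ids$succ)$vmax / 10
  mh <- set_reaction_bounds(mm, ids$co2, -up / 2,
                            mm$reactions[[ids$co2]]$ub)
  y_half <- fva(mh, 0.99, ids$succ)$vmax / 10
  c(full = y_full, half = y_half,
    drop_percent = 100 * (y_full - y_half) / y_full)
})

panel_path <- get_arg("--panel")
if (!is.null(panel_path)) {
  panel <- utils::read.table(panel_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  panel$observed <- as.logical(panel$observed)
  rp <- run_panel(m, panel)
  print(rp$confusion)
  res$panel <- unclass(rp$confusion)[c("tp", "fp", "fn", "tn", "percent")]
  utils::write.table(rp$calls, file.path(out_dir, "panel_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(res, file.path(out_dir, "ibp722_repro.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", file.path(out_dir, "ibp722_repro.json"))
}
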