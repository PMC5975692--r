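# Taxonomy-weighted EC scoring, assignment and subunit grouping.

test_that("taxonomy weight is the shared-prefix rank fraction", {
  q <- ASUC_QUERY_LINEAGE
  expect_equal(taxonomy_weight(q, q), 1)
  expect_equal(taxonomy_weight(q, lin7(4)), 4 / 7)
  expect_equal(taxonomy_weight(q, lin7(0)), 0)
  # string form parses too
  expect_equal(taxonomy_weight(paste(q, collapse = ";"),
                               paste(lin7(4), collapse = ";")), 4 / 7)
  expect_error(taxonomy_weight(q, character(0)), "empty lineage")
})

test_that("functional scores: unanimity, ties, and EC-less hits", {
  s <- functional_score(hit_df(rep("1.1.1.1", 10)))
  expect_equal(s$score, 1)
  expect_equal(s$support, 10)
  tied <- functional_score(hit_df(c(rep("1.1.1.1", 5), rep("2.7.2.1", 5))))
  expect_equal(tied$score, c(0.5, 0.5))
  expect_true(attr(tied, "tie"))
  # hits without EC dilute the denominator only
  half <- functional_score(hit_df(c(rep("1.1.1.1", 5), rep("", 5))))
  expect_equal(half$score, 0.5)
  expect_equal(sum(half$score), 0.5)
  none <- functional_score(hit_df(rep("", 4)))
  expect_equal(nrow(none), 0)
  expect_true(attr(none, "no_metabolic_function"))
  # full annotation: scores sum to exactly one
  mixed <- functional_score(hit_df(c("1.1.1.1", "2.7.2.1", "1.1.1.1"),
                                   score = c(90, 50, 20),
                                   lineage = c(
                                     paste(lin7(7), collapse = ";"),
                                     paste(lin7(3), collapse = ";"),
                                     paste(lin7(5), collapse = ";"))))
  expect_equal(sum(mixed$score), 1, tolerance = 1e-12)
})

test_that("scores are permutation invariant and taxonomy-monotone", {
  h <- synth_hit_table(11, truth_fraction = 0.6)
  s1 <- functional_score(h)
  s2 <- functional_score(h[sample.int(nrow(h)), ])
  expect_equal(s1, s2, ignore_attr = TRUE)
  # raising the taxonomy weight of truth-carrying hits never lowers truth
  h2 <- h
  truth <- h2$ec == "1.1.1.37"
  h2$lineage[truth] <- paste(ASUC_QUERY_LINEAGE, collapse = ";")
  s3 <- functional_score(h2)
  get <- function(s) s$score[s$ec == "1.1.1.37"]
  expect_gte(get(s3), get(s1) - 1e-12)
})

test_that("partial EC annotations earn configurable partial credit", {
  h <- hit_df(c("2.7.1.11", "2.7.1.-", "3.6.1.1"))
  s <- functional_score(h)
  full <- s$score[s$ec == "2.7.1.11"]
  # exact hit (1/3) plus partial support (0.5/3)
  expect_equal(full, (1 + 0.5) / 3, tolerance = 1e-12)
  s0 <- functional_score(h, partial_credit = 0)
  expect_equal(s0$score[s0$ec == "2.7.1.11"], 1 / 3, tolerance = 1e-12)
})

test_that("assignment honours threshold, ties and gap-filling retention", {
  h_hi <- hit_df(c(rep("1.1.1.1", 9), "2.7.2.1"), query = "gA")
  h_tie <- hit_df(c(rep("1.1.1.1", 5), rep("2.7.2.1", 5)), query = "gB")
  h_lo <- hit_df(c("1.1.1.1", "1.1.1.1", "2.7.2.1", "3.6.1.1", "5.3.1.9"),
                 query = "gC")   # top candidate at 0.4: below threshold
  h_no <- hit_df(rep("", 3), query = "gD")
  all_hits <- rbind(h_hi, h_tie, h_lo, h_no)
  a <- assign_functions(all_hits, accept_threshold = 0.5)
  a <- a[order(a$gene), ]
  expect_equal(a$status,
               c("assigned", "manual-review", "unassigned",
                 "no-metabolic-function"))
  expect_equal(a$ec[a$gene == "gA"], "1.1.1.1")
  # the unassigned CDS keeps its best candidate for later review
  expect_equal(a$ec[a$gene == "gC"], "1.1.1.1")
})

test_that("subunit grouping joins complexes with and, isozymes with or", {
  asg <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    ec = c("1.3.5.4", "1.3.5.4", "1.1.1.1", "1.1.1.1", "9.9.9.9"),
    score = 0.9, status = "assigned", stringsAsFactors = FALSE)
  cat0 <- data.frame(ec = c("1.3.5.4", "1.1.1.1"),
                     multimeric = c(TRUE, FALSE))
  expect_warning(g <- group_subunits(asg, cat0), "9.9.9.9")
  g <- g[order(g$ec), ]
  expect_equal(g$gene_association[g$ec == "1.3.5.4"], "(g1 and g2)")
  expect_equal(g$gene_association[g$ec == "1.1.1.1"], "(g3 or g4)")
  expect_equal(g$gene_association[g$ec == "9.9.9.9"], "g5")
  expect_equal(g$class[g$ec == "1.3.5.4"], "complex")
})

test_that("planted-truth tables: top-1 recovery across seeded replicates", {
  # deterministic single-case check first (seed 42 of the generator)
  h42 <- synth_hit_table(42, n_hits = 20, truth_fraction = 0.7,
                         taxonomy_bias = TRUE)
  s42 <- functional_score(h42)
  expect_equal(s42$ec[1], "1.1.1.37")
  expect_false(attr(s42, "tie"))
  # 200 replicates at truth fraction 0.7 with bias: recovery must be total
  hits <- vapply(1:200, function(seed) {
    h <- synth_hit_table(seed, true_ec = "4.1.1.49", n_hits = 20,
                         truth_fraction = 0.7, taxonomy_bias = TRUE)
    s <- functional_score(h)
    s$ec[1] == "4.1.1.49" && !attr(s, "tie")
  }, TRUE)
  expect_equal(mean(hits), 1)
})

test_that("hit tables round-trip through the TSV reader", {
  h <- synth_hit_table(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_hit_table(path)
  expect_equal(back$ec, h$ec)
  expect_equal(back$score, h$score, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_hit_table(bad), "columns")
})
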