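# Taxonomy-weighted EC-number functional scoring of homology hits and
# putative function assignment.
#
# For one query, every hit contributes weight w = w_tax * w_sim, where
# w_sim is the hit's similarity score normalised by the best hit and w_tax
# the shared-lineage fraction with the query. A candidate EC scores
# sum(w over hits carrying it) / sum(w over all hits), which lies in [0, 1]
# and reaches 1 when every hit supports the same EC.

#' Taxonomic similarity weight between two lineages
#'
#' The fraction of ranks shared from the root down (domain first): 1 for
#' identical lineages, 0 when even the first rank differs.
#'
#' @param query_lineage,subject_lineage character vectors of ranks ordered
#'   root to leaf (or single `";"`-separated strings).
#' @param ranks total number of ranks in the scheme (default: the longer of
#'   the two lineages).
#' @return weight in [0, 1].
#' @export
taxonomy_weight <- function(query_lineage, subject_lineage, ranks = NULL) {
  split1 <- function(x) if (length(x) == 1 && grepl(";", x))
    trimws(strsplit(x, ";", fixed = TRUE)[[1]]) else x
  q <- split1(query_lineage); s <- split1(subject_lineage)
  if (!length(q) || !length(s))
    stop("empty lineage with taxonomy weighting enabled")
  if (is.null(ranks)) ranks <- max(length(q), length(s))
  k <- 0
  for (i in seq_len(min(length(q), length(s)))) {
    if (q[i] == s[i]) k <- k + 1 else break
  }
  k / ranks
}

# Credit a hit's EC annotation gives to a candidate EC: exact match 1;
# a partial EC (e.g. "2.7.1.-") matching the candidate's prefix earns the
# configured partial credit (and symmetrically for a partial candidate).
ec_match_credit <- function(candidate, hit_ec, partial_credit = 0.5) {
  if (candidate == hit_ec) return(1)
  is_partial <- function(x) grepl("\\.-", x) || endsWith(x, "-")
  prefix <- function(x) sub("(\\.-)+$", "", x)
  if (is_partial(hit_ec) && !is_partial(candidate) &&
      startsWith(candidate, paste0(prefix(hit_ec), ".")))
    return(partial_credit)
  if (is_partial(candidate) && !is_partial(hit_ec) &&
      startsWith(hit_ec, paste0(prefix(candidate), ".")))
    return(partial_credit)
  0
}

#' Taxonomy-weighted EC frequency scores for one query
#'
#' @param hits data.frame with columns `query`, `subject`, `score`
#'   (non-negative similarity, e.g. bit score), `ec` (possibly empty or
#'   `";"`-separated, partial ECs like `"2.7.1.-"` allowed) and `lineage`
#'   (`";"`-separated subject lineage). One query per call.
#' @param query_lineage the query organism's lineage.
#' @param partial_credit weight credit a partial EC gives its completions.
#' @param use_taxonomy disable to weight by similarity only.
#' @return data.frame `query`, `ec`, `score` (in [0, 1]), `support` (number
#'   of contributing hits), sorted by decreasing score (ties broken by EC
#'   string); attribute `tie` flags a tie at the top, attribute
#'   `no_metabolic_function` is `TRUE` when no hit carries any EC.
#' @export
functional_score <- function(hits, query_lineage = ASUC_QUERY_LINEAGE,
                             partial_credit = 0.5, use_taxonomy = TRUE) {
  stopifnot(nrow(hits) >= 1)
  if (length(unique(hits$query)) != 1)
    stop("functional_score expects hits of a single query; use ",
         "assign_functions for whole tables")
  if (any(hits$score < 0)) stop("similarity scores must be non-negative")
  w_sim <- if (max(hits$score) > 0) hits$score / max(hits$score)
  else rep(1, nrow(hits))
  w_tax <- if (use_taxonomy) {
    vapply(hits$lineage, function(l)
      taxonomy_weight(query_lineage, l), 0, USE.NAMES = FALSE)
  } else rep(1, nrow(hits))
  w <- w_tax * w_sim
  denom <- sum(w)
  ecs_per_hit <- lapply(hits$ec, function(e) {
    if (is.na(e) || !nzchar(e)) character(0)
    else trimws(strsplit(e, ";", fixed = TRUE)[[1]])
  })
  candidates <- sort(unique(unlist(ecs_per_hit)))
  out <- data.frame(query = character(0), ec = character(0),
                    score = numeric(0), support = integer(0))
  if (!length(candidates) || denom <= 0) {
    attr(out, "no_metabolic_function") <- TRUE
    attr(out, "tie") <- FALSE
    return(out)
  }
  rows <- lapply(candidates, function(cand) {
    credit <- vapply(ecs_per_hit, function(es) {
      if (!length(es)) return(0)
      max(vapply(es, ec_match_credit, 0, candidate = cand,
                 partial_credit = partial_credit))
    }, 0)
    data.frame(query = hits$query[1], ec = cand,
               score = sum(credit * w) / denom,
               support = sum(credit > 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$ec), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_metabolic_function") <- FALSE
  attr(out, "tie") <- nrow(out) >= 2 &&
    abs(out$score[1] - out$score[2]) < 1e-9
  out
}

#' Assign putative functions from EC scores
#'
#' The top-scoring EC per query is assigned when its score reaches the
#' acceptance threshold and no second candidate ties it (tolerance 1e-9);
#' ties are marked `"manual-review"` and sub-threshold queries
#' `"unassigned"` (retained for later gap-filling revisits). Queries with
#' no EC evidence are `"no-metabolic-function"`.
#'
#' @param hits full hit table (any number of queries) with the
#'   [functional_score()] columns.
#' @param accept_threshold minimal accepted score.
#' @param query_lineage lineage of the query organism.
#' @param ... passed to [functional_score()].
#' @return data.frame `gene`, `ec`, `score`, `status`.
#' @export
assign_functions <- function(hits, accept_threshold = 0.5,
                             query_lineage = ASUC_QUERY_LINEAGE, ...) {
  rows <- lapply(split(hits, hits$query), function(h) {
    sc <- functional_score(h, query_lineage, ...)
    if (attr(sc, "no_metabolic_function") || !nrow(sc))
      return(data.frame(gene = h$query[1], ec = NA_character_,
                        score = NA_real_, status = "no-metabolic-function",
                        stringsAsFactors = FALSE))
    status <- if (attr(sc, "tie")) "manual-review"
    else if (sc$score[1] >= accept_threshold) "assigned"
    else "unassigned"
    data.frame(gene = h$query[1], ec = sc$ec[1], score = sc$score[1],
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group assigned CDSs into enzyme complexes or isozyme sets
#'
#' CDSs sharing a multimeric EC are joined with `and` (subunits of one
#' complex); CDSs sharing a monomeric EC with `or` (isozymes). ECs absent
#' from the catalog default to `or` with a warning.
#'
#' @param assignments data.frame from [assign_functions()] (only
#'   `"assigned"` rows are grouped).
#' @param subunit_catalog data.frame with columns `ec` and `multimeric`
#'   (logical).
#' @return data.frame `ec`, `genes` (`";"`-joined), `n`,
#'   `gene_association` (boolean text), `class`.
#' @export
group_subunits <- function(assignments, subunit_catalog) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  rows <- lapply(split(a, a$ec), function(g) {
    ec <- g$ec[1]
    genes <- sort(unique(g$gene))
    in_cat <- ec %in% subunit_catalog$ec
    multi <- if (in_cat)
      isTRUE(subunit_catalog$multimeric[match(ec, subunit_catalog$ec)])
    else {
      warning("EC ", ec, " absent from subunit catalog; defaulting to ",
              "isozymes (or)")
      FALSE
    }
    gpr <- if (length(genes) == 1) genes
    else paste0("(", paste(genes, collapse = if (multi) " and " else " or "),
                ")")
    data.frame(ec = ec, genes = paste(genes, collapse = ";"),
               n = length(genes), gene_association = gpr,
               class = if (multi) "complex" else "isozymes",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a homology hit table
#'
#' Tab-separated with header; requires columns query, subject, score, ec,
#' lineage (BLAST outfmt-6-like plus EC and lineage annotations).
#'
#' @param path TSV file.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("query", "subject", "score", "ec", "lineage")
  if (!all(need %in% names(h)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  h
}
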