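# Hand-built homology-hit tables for annotation tests.

lin7 <- function(k, tag = "x") {
  ranks <- ASUC_QUERY_LINEAGE
  c(ranks[seq_len(k)],
    if (k < 7) paste0("alt_", tag, "_", seq_len(7 - k)))
}

hit_df <- function(ec, score = rep(100, length(ec)),
                   lineage = rep(paste(ASUC_QUERY_LINEAGE, collapse = ";"),
                                 length(ec)),
                   query = "q1") {
  data.frame(query = query,
             subject = sprintf("s%02d", seq_along(ec)),
             score = score, ec = ec, lineage = lineage,
             stringsAsFactors = FALSE)
}
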