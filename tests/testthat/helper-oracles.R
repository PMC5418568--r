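# Independent brute-force oracles kept deliberately separate from the
# implementation paths they check.

# Exhaustive rule-enumeration classifier: every candidate (predicate, label)
# is listed explicitly and tried in order; the first satisfied predicate
# wins. Predicates only read raw case fields.
oracle_classify <- function(case) {
  s <- case$ihc$stains
  absent <- names(s)[s == "absent"]
  pat <- if ("MLH1" %in% absent) "MLH1_PMS2"
    else if ("MSH2" %in% absent) "MSH2_MSH6"
    else if (all(c("MSH6", "PMS2") %in% absent)) "PMS2_only"
    else if ("MSH6" %in% absent) "MSH6_only"
    else if ("PMS2" %in% absent) "PMS2_only"
    else "normal"
  g <- if (case$genotyped) case$germline else variant_table()
  g_path <- g[g$path_class %in% c("4", "5") | g$truncating | g$designated, ]
  som <- case$somatic
  som_path <- if (is.null(som)) variant_table() else {
    v <- som$variants
    v[v$origin == "somatic" &
        (v$path_class %in% c("4", "5") | v$truncating | v$designated), ]
  }
  loh_strong <- !is.null(som) && som$loh %in% c("likely", "definite")
  loh_maybe <- !is.null(som) && som$loh == "maybe"
  meth_pos <- !is.null(case$methylation) &&
    case$methylation$call == "positive"
  meth_failed <- is.null(case$methylation) ||
    case$methylation$call == "failed"
  meth_near <- !is.null(case$methylation) &&
    case$methylation$call == "negative" &&
    case$methylation$mean_level >= 13
  braf_pos <- case$braf_ihc == "positive"
  conc <- switch(pat, MLH1_PMS2 = c("MLH1", "PMS2", "EPCAM"),
                 MSH2_MSH6 = c("MSH2", "MSH6", "EPCAM"),
                 MSH6_only = "MSH6", PMS2_only = c("PMS2", "MLH1"),
                 c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM"))
  carrier_conc <- any(g_path$gene %in% conc)
  second_hit <- function(gene) {
    !is.null(som) && !som$failed &&
      (any(som$variants$gene[som$variants$origin == "somatic"] == gene) ||
         loh_strong)
  }
  two_hits_one_gene <- nrow(som_path) &&
    max(table(som_path$gene)) >= 2
  one_hit <- nrow(som_path) >= 1

  rules <- list(
    list(function() pat == "normal" && !carrier_conc, "pMMR"),
    list(function() pat == "normal" && carrier_conc &&
           (is.null(som) || som$failed ||
              second_hit(g_path$gene[1])), "LS"),
    list(function() pat == "normal" && carrier_conc, "LS_sporadic_tumour"),
    list(function() pat == "MLH1_PMS2" && meth_pos, "MLH1_hm"),
    list(function() pat == "MLH1_PMS2" && braf_pos &&
           ((meth_failed && case$specimen == "biopsy") || meth_near),
         "MLH1_hm"),
    list(function() carrier_conc &&
           (is.null(som) || som$failed || second_hit(g_path$gene[1])), "LS"),
    list(function() carrier_conc, "LS_sporadic_tumour"),
    list(function() !is.null(som) && !som$failed &&
           (two_hits_one_gene || (one_hit && loh_strong)),
         "double_somatic"),
    list(function() !is.null(som) && !som$failed && one_hit && loh_maybe,
         "possibly_double_somatic"),
    list(function() TRUE, "unexplained"))
  for (rule in rules) if (isTRUE(rule[[1]]())) return(rule[[2]])
  "unexplained"
}

# literal per-pair transcription of the three discordance criteria, using a
# mate lookup table instead of the per-read flag fields
oracle_discordant <- function(reads, stats) {
  vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    mates <- reads[reads$qname == r$qname, ]
    mate <- mates[mates$flag != r$flag | mates$pos != r$pos, ][1, ]
    if (is.na(mate$rname) || mate$rname != r$rname) return(TRUE)
    self_rev <- bitwAnd(r$flag, 16L) != 0L
    mate_rev_actual <- bitwAnd(mate$flag, 16L) != 0L
    if (self_rev == mate_rev_actual) return(TRUE) # FF / RR
    if (r$pos != mate$pos) {
      left_fwd <- if (r$pos < mate$pos) !self_rev else !mate_rev_actual
      if (!left_fwd) return(TRUE) # RF
    }
    abs(abs(r$tlen) - stats$mean) > 3 * stats$sd
  }, TRUE)
}

# expected carrier fraction among cases under the prospective logistic model
oracle_case_carrier_fraction <- function(f, baseline, or) {
  p1 <- plogis(qlogis(baseline) + log(or))
  f * p1 / (f * p1 + (1 - f) * baseline)
}

make_read <- function(qname = "q", flag = 99L, rname = "cA", pos = 100L,
                      mapq = 60L, cigar = "100M", rnext = "cA",
                      pnext = 300L, tlen = 300L, seq = strrep("A", 100),
                      qual = strrep("H", 100)) {
  tibble::tibble(qname = qname, flag = as.integer(flag), rname = rname,
                 pos = as.integer(pos), mapq = as.integer(mapq),
                 cigar = cigar, rnext = rnext, pnext = as.integer(pnext),
                 tlen = as.integer(tlen), seq = seq, qual = qual)
}
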