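# Per-case etiology cascade, cross-tabulation, screening performance and
# prevalence arithmetic.

#' Construct a case record
#'
#' One screened colorectal-cancer patient: demographics, specimen type,
#' stain results, methylation and BRAF work-up, and germline/somatic variant
#' evidence. Non-genotyped cases must not carry germline variant records.
#'
#' @param case_id character identifier
#' @param ihc an [ihc_result()]
#' @param sex `"male"` or `"female"`
#' @param age_dx age at diagnosis (years)
#' @param location tumour site: `right`, `left` or `rectum`
#' @param stage `I`..`IV` or `unknown`
#' @param specimen `"resection"` or `"biopsy"`
#' @param genotyped logical; germline genotyping performed
#' @param methylation a `methylation_result`, or `NULL` if not tested
#' @param braf_ihc `positive`, `negative` or `not_done`
#' @param germline tibble of germline [variant_record()]s
#' @param somatic a [somatic_profile()] or `NULL`
#' @param etiology_true optional generator truth label (never read by the
#'   classifier)
#' @return a `case_record` list
#' @export
case_record <- function(case_id, ihc, sex = "male", age_dx = 65,
                        location = "right", stage = "II",
                        specimen = "resection", genotyped = FALSE,
                        methylation = NULL, braf_ihc = "not_done",
                        germline = variant_table(), somatic = NULL,
                        etiology_true = NA_character_) {
  stopifnot(inherits(ihc, "ihc_result"))
  if (!genotyped && nrow(germline)) {
    stop("non-genotyped cases cannot carry germline variant records",
         call. = FALSE)
  }
  structure(list(case_id = as.character(case_id), sex = sex,
                 age_dx = age_dx, location = location, stage = stage,
                 specimen = specimen, genotyped = isTRUE(genotyped),
                 ihc = ihc, methylation = methylation, braf_ihc = braf_ihc,
                 germline = germline, somatic = somatic,
                 etiology_true = etiology_true),
            class = "case_record")
}

# germline genes concordant with an abnormal stain pattern
.concordant_genes <- function(pattern) {
  switch(pattern,
         MLH1_PMS2 = c("MLH1", "PMS2", "EPCAM"),
         MSH2_MSH6 = c("MSH2", "MSH6", "EPCAM"),
         MSH6_only = "MSH6",
         PMS2_only = c("PMS2", "MLH1"),
         .mmr_genes_ep)
}

# germline variants that qualify as the Lynch-syndrome hit: directly
# pathogenic (class 4/5, truncating, or study-designated), restricted to
# `genes` when given. Class-3 qualification via a tumour second hit is
# handled inside resolve_double_somatic().
.qualifying_germline <- function(germline, genes = .mmr_genes_ep) {
  g <- germline[germline$gene %in% genes, , drop = FALSE]
  g[.is_pathogenic(g), , drop = FALSE]
}

.map_resolution <- function(res) {
  switch(res,
         solved_double_somatic = "double_somatic",
         possibly_double_somatic = "possibly_double_somatic",
         lynch_second_hit = "LS",
         lynch_sporadic_tumour = "LS_sporadic_tumour",
         not_solved = "unexplained")
}

#' Classify one case through the etiology cascade
#'
#' Decision order. (1) Normal or incomplete stain pattern: a genotyped
#' carrier of a qualifying germline mutation is Lynch syndrome — attributed
#' to the mutation when the tumour shows a second hit (or was never
#' sequenced), or called a sporadic tumour in a carrier when sequencing
#' found none; everyone else is MMR-proficient. (2) MLH1/PMS2 loss:
#' methylation-positive (directly or via the BRAF reflex) is sporadic
#' hypermethylation; otherwise a qualifying germline mutation in a
#' concordant gene means Lynch syndrome; otherwise the tumour-sequencing
#' resolution decides; with no usable tumour test the case is unexplained.
#' (3) Other loss patterns: as (2) without the methylation step.
#'
#' @param case a [case_record()]
#' @param config settings list from [default_config()]
#' @return an `etiology_call` list: `label`, `pattern`, `evidence_chain`
#' @export
classify_case <- function(case, config = default_config()) {
  stopifnot(inherits(case, "case_record"))
  if (is.null(case$ihc)) stop("case has no IHC result", call. = FALSE)
  thr <- config$screening$methylation_threshold
  margin <- config$screening$braf_rescue_margin
  pattern <- loss_pattern(case$ihc)
  evidence <- sprintf("ihc_pattern=%s", pattern)
  germline <- if (case$genotyped) case$germline else variant_table()

  finish <- function(label, ...) {
    structure(list(label = label, pattern = as.character(pattern),
                   weak_stains = attr(pattern, "weak"),
                   evidence_chain = c(evidence, ...)),
              class = "etiology_call")
  }

  if (pattern %in% c("normal", "incomplete")) {
    carrier <- .qualifying_germline(germline)
    if (nrow(carrier)) {
      if (!is.null(case$somatic) && !case$somatic$failed) {
        res <- resolve_double_somatic(case$somatic, germline)
        return(finish(.map_resolution(res),
                      sprintf("germline_carrier=%s", carrier$gene[1]),
                      sprintf("somatic_resolution=%s", res)))
      }
      return(finish("LS",
                    sprintf("germline_carrier=%s", carrier$gene[1]),
                    "tumour_not_sequenced"))
    }
    return(finish("pMMR"))
  }

  if (pattern == "MLH1_PMS2") {
    meth_pos <- !is.null(case$methylation) &&
      case$methylation$call == "positive"
    if (meth_pos) {
      return(finish("MLH1_hm", "methylation=positive"))
    }
    braf <- braf_fallback(case$specimen, case$methylation, case$braf_ihc,
                          threshold = thr, margin = margin)
    if (braf == "infer_mlh1_hm") {
      return(finish("MLH1_hm", "braf_reflex=infer_mlh1_hm"))
    }
  }

  genes <- .concordant_genes(as.character(pattern))
  carrier <- .qualifying_germline(germline, genes)
  if (nrow(carrier)) {
    if (!is.null(case$somatic) && !case$somatic$failed) {
      res <- resolve_double_somatic(case$somatic, germline)
      return(finish(.map_resolution(res),
                    sprintf("germline_carrier=%s", carrier$gene[1]),
                    sprintf("somatic_resolution=%s", res)))
    }
    return(finish("LS", sprintf("germline_carrier=%s", carrier$gene[1]),
                  "tumour_not_sequenced"))
  }
  if (!is.null(case$somatic)) {
    res <- resolve_double_somatic(case$somatic, germline)
    return(finish(.map_resolution(res),
                  sprintf("somatic_resolution=%s", res)))
  }
  finish("unexplained", "no_tumour_sequencing")
}

#' Classify every case of a cohort
#'
#' @param cohort list of [case_record()]s
#' @param config settings list
#' @return tibble: `case_id`, `label`, `pattern`, `genotyped`,
#'   `etiology_true`, and the per-case evidence chain as a list column
#' @export
classify_cohort <- function(cohort, config = default_config()) {
  calls <- lapply(cohort, classify_case, config = config)
  tibble::tibble(
    case_id = vapply(cohort, function(x) x$case_id, ""),
    label = vapply(calls, function(x) x$label, ""),
    pattern = vapply(calls, function(x) x$pattern, ""),
    genotyped = vapply(cohort, function(x) x$genotyped, TRUE),
    etiology_true = vapply(cohort, function(x) x$etiology_true, ""),
    evidence = lapply(calls, function(x) x$evidence_chain)
  )
}

# grouped labels used by tables and reports: sporadic-tumour carriers count
# as LS; possibly-double-somatic counts as double somatic
.group_label <- function(label) {
  out <- label
  out[label == "LS_sporadic_tumour"] <- "LS"
  out[label == "possibly_double_somatic"] <- "double_somatic"
  out
}

#' Cross-tabulate stain pattern by etiology
#'
#' Builds the abnormal-IHC contingency table: one row per loss pattern, one
#' column per deficiency etiology, with row totals. Lynch-syndrome cases
#' with normal stains are excluded from the table body and reported in the
#' `normal_ihc_ls` attribute; sporadic-tumour carriers count under LS and
#' possibly-double-somatic under double somatic.
#'
#' @param calls classification tibble from [classify_cohort()]
#' @return tibble with attribute `normal_ihc_ls`
#' @export
tabulate_etiology <- function(calls) {
  patterns <- c("MLH1_PMS2", "MSH2_MSH6", "MSH6_only", "PMS2_only")
  cols <- c("MLH1_hm", "LS", "double_somatic", "unexplained")
  grouped <- .group_label(calls$label)
  abn <- calls$pattern %in% patterns
  tab <- matrix(0L, nrow = length(patterns), ncol = length(cols),
                dimnames = list(patterns, cols))
  if (any(abn)) {
    xt <- table(factor(calls$pattern[abn], levels = patterns),
                factor(grouped[abn], levels = cols))
    tab[] <- as.integer(xt)
  }
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "pattern")
  out$total <- as.integer(rowSums(tab))
  total_row <- tibble::tibble(pattern = "Total")
  for (cc in c(cols, "total")) total_row[[cc]] <- sum(out[[cc]])
  out <- dplyr::bind_rows(out, total_row)
  attr(out, "normal_ihc_ls") <-
    sum(!abn & grouped == "LS")
  out
}

#' Screening performance of IHC for Lynch-syndrome detection
#'
#' Evaluated on the genotyped subset only, since germline truth is unknown
#' elsewhere. A case screens positive when its stain pattern is abnormal
#' and the deficiency is not explained by MLH1 hypermethylation; truth
#' positive means the case carries a qualifying germline Lynch-syndrome
#' mutation (sporadic-tumour carriers included). Percentages are rounded
#' half away from zero to one decimal at report time only.
#'
#' @param cohort list of [case_record()]s
#' @param calls matching tibble from [classify_cohort()]
#' @return list with counts (`tp`, `fp`, `tn`, `fn`), `n_evaluated`,
#'   percent metrics, and explicit denominators
#' @export
screening_performance <- function(cohort, calls) {
  stopifnot(length(cohort) == nrow(calls))
  geno <- calls$genotyped
  if (!any(geno)) stop("no genotyped cases to evaluate", call. = FALSE)
  abn <- calls$pattern %in% c("MLH1_PMS2", "MSH2_MSH6", "MSH6_only",
                              "PMS2_only")
  screen_pos <- abn & calls$label != "MLH1_hm"
  truth <- vapply(cohort, function(cs) {
    cs$genotyped && nrow(.qualifying_germline(cs$germline)) > 0
  }, TRUE)

  tp <- sum(geno & screen_pos & truth)
  fp <- sum(geno & screen_pos & !truth)
  fn <- sum(geno & !screen_pos & truth)
  tn <- sum(geno & !screen_pos & !truth)
  denom_check <- function(d, what) {
    if (d == 0) stop("undefined metric: zero denominator for ", what,
                     call. = FALSE)
    d
  }
  pct <- function(num, den) round_half_up(100 * num / den, 1)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn, n_evaluated = sum(geno),
    sensitivity = pct(tp, denom_check(tp + fn, "sensitivity")),
    specificity = pct(tn, denom_check(tn + fp, "specificity")),
    ppv = pct(tp, denom_check(tp + fp, "PPV")),
    npv = pct(tn, denom_check(tn + fn, "NPV")),
    denominators = c(sensitivity = tp + fn, specificity = tn + fp,
                     ppv = tp + fp, npv = tn + fn)
  )
}

# gene credited with a case's deficiency, for share-of-etiology reports
.attributed_gene <- function(case, call) {
  if (call$label %in% c("LS", "LS_sporadic_tumour")) {
    g <- .qualifying_germline(case$germline)
    if (nrow(g)) return(g$gene[1])
    return(NA_character_)
  }
  if (call$label == "double_somatic" && !is.null(case$somatic)) {
    som <- case$somatic$variants
    som <- som[som$origin == "somatic" & .is_pathogenic(som), , drop = FALSE]
    if (nrow(som)) return(names(sort(table(som$gene), decreasing = TRUE))[1])
  }
  if (call$label == "possibly_double_somatic") {
    # adjudicated by the stain pattern, which names the deficient protein
    return(switch(call$pattern, MSH6_only = "MSH6", PMS2_only = "PMS2",
                  MSH2_MSH6 = "MSH2", MLH1_PMS2 = "MLH1", NA_character_))
  }
  NA_character_
}

#' Cohort proportion report
#'
#' Deficiency and etiology fractions with explicit numerators and
#' denominators: the dMMR fraction, per-etiology cohort fractions, the
#' MSH6+PMS2 share of Lynch-syndrome cases and the MLH1+MSH2 share of
#' double-somatic cases (each case attributed to one gene).
#'
#' @param cohort list of [case_record()]s
#' @param calls matching tibble from [classify_cohort()]
#' @return nested list of `(numerator, denominator, percent)` entries
#' @export
cohort_proportions <- function(cohort, calls) {
  n <- nrow(calls)
  grouped <- .group_label(calls$label)
  abn <- calls$pattern %in% c("MLH1_PMS2", "MSH2_MSH6", "MSH6_only",
                              "PMS2_only")
  frac <- function(num, den) {
    list(numerator = num, denominator = den,
         percent = if (den > 0) round_half_up(100 * num / den, 1) else NA_real_)
  }
  full_calls <- lapply(cohort, classify_case)
  genes <- mapply(.attributed_gene, cohort, full_calls)
  is_ls <- grouped == "LS"
  is_ds <- grouped == "double_somatic"
  list(
    dMMR = frac(sum(abn), n),
    LS_prevalence = frac(sum(is_ls), n),
    MLH1_hm = frac(sum(grouped == "MLH1_hm"), n),
    double_somatic = frac(sum(is_ds), n),
    unexplained = frac(sum(grouped == "unexplained" & abn), n),
    msh6_pms2_share_of_ls = frac(sum(is_ls & genes %in% c("MSH6", "PMS2"),
                                     na.rm = TRUE), sum(is_ls)),
    mlh1_msh2_share_of_double_somatic =
      frac(sum(is_ds & genes %in% c("MLH1", "MSH2"), na.rm = TRUE),
           sum(is_ds))
  )
}
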