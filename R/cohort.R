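# Synthetic cohort generation and the deterministic fixture cohort that
# reconstructs the published study marginals.

#' Cohort generator configuration
#'
#' @param n_cases number of colorectal-cancer cases
#' @param etiology_mix named proportions over `pMMR`, `LS`, `MLH1_hm`,
#'   `double_somatic`, `unexplained`; must sum to 1. The default is the
#'   published cohort mixture (1044/27/90/16/5 out of 1182).
#' @param genotyped_fraction_normal_ihc fraction of normal-IHC cases with
#'   germline genotyping (abnormal-IHC cases are always genotyped)
#' @param founder_freqs named carrier frequencies for the imputable founder
#'   mutations (population context; carried in the config for downstream
#'   prevalence arithmetic)
#' @param weak_stain_rate fraction of MSH6-mutation Lynch cases presenting a
#'   weak-but-present stain (hence normal pattern) instead of MSH6 loss
#' @param sporadic_in_carrier_count number of Lynch-mutation carriers whose
#'   tumour shows no second hit (sporadic tumour in a carrier)
#' @param exact logical; apportion etiology counts by largest remainder
#'   instead of a multinomial draw
#' @param seed integer RNG seed
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_cases = 1182L,
                          etiology_mix = c(pMMR = 1044, LS = 27, MLH1_hm = 90,
                                           double_somatic = 16,
                                           unexplained = 5) / 1182,
                          genotyped_fraction_normal_ihc = 821 / 1050,
                          founder_freqs = founder_carrier_freqs(),
                          weak_stain_rate = 1 / 3,
                          sporadic_in_carrier_count = 2L,
                          exact = FALSE, seed = 1L) {
  lbl <- c("pMMR", "LS", "MLH1_hm", "double_somatic", "unexplained")
  if (!setequal(names(etiology_mix), lbl)) {
    stop("etiology_mix must be named over: ", paste(lbl, collapse = ", "),
         call. = FALSE)
  }
  etiology_mix <- etiology_mix[lbl]
  .check_fraction(etiology_mix, "etiology_mix")
  if (abs(sum(etiology_mix) - 1) > 1e-12) {
    stop("etiology_mix must sum to 1", call. = FALSE)
  }
  .check_fraction(genotyped_fraction_normal_ihc,
                  "genotyped_fraction_normal_ihc")
  .check_fraction(weak_stain_rate, "weak_stain_rate")
  .check_fraction(founder_freqs, "founder_freqs")
  structure(list(n_cases = as.integer(n_cases), etiology_mix = etiology_mix,
                 genotyped_fraction_normal_ihc = genotyped_fraction_normal_ihc,
                 founder_freqs = founder_freqs,
                 weak_stain_rate = weak_stain_rate,
                 sporadic_in_carrier_count = as.integer(sporadic_in_carrier_count),
                 exact = isTRUE(exact), seed = as.integer(seed)),
            class = "cohort_config")
}

# largest-remainder apportionment of n among probs
.apportion <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.ihc_for_pattern <- function(pattern, weak_pct = NA) {
  s <- stats::setNames(rep("present", 4L), .mmr_genes)
  s[switch(pattern,
           MLH1_PMS2 = c("MLH1", "PMS2"),
           MSH2_MSH6 = c("MSH2", "MSH6"),
           MSH6_only = "MSH6",
           PMS2_only = "PMS2",
           normal = character(0))] <- "absent"
  pct <- NULL
  if (!is.na(weak_pct)) {
    s[["MSH6"]] <- "weak_present"
    pct <- c(MSH6 = weak_pct)
  }
  ihc_result(s, percent_positive = pct)
}

# decorate a list of cases with sex/age/stage/location drawn from the
# per-etiology descriptive distributions; realism only, never classified on
.decorate_cases <- function(cases, etiology) {
  demo <- .demography_defaults()
  idx_by <- split(seq_along(cases), etiology)
  for (et in names(idx_by)) {
    d <- demo[[if (et %in% names(demo)) et else "pMMR"]]
    idx <- idx_by[[et]]
    k <- length(idx)
    n_male <- round(k * d$male)
    sexes <- rep(c("male", "female"), c(n_male, k - n_male))
    stages <- rep(names(d$stage), .apportion(k, d$stage + 1e-9))
    locs <- rep(names(d$loc), .apportion(k, d$loc))
    # triangular spread between the printed quartiles around the median
    ages <- round(d$age[2] + (seq_len(k) %% 7 - 3) / 3 *
                    (d$age[3] - d$age[1]) / 2)
    for (j in seq_len(k)) {
      cases[[idx[j]]]$sex <- sexes[j]
      cases[[idx[j]]]$stage <- stages[j]
      cases[[idx[j]]]$location <- locs[j]
      cases[[idx[j]]]$age_dx <- ages[j]
    }
  }
  cases
}

# a two-hit somatic profile for generated double-somatic cases
.synthetic_ds_profile <- function(gene, use_loh, msings) {
  v1 <- variant_record(gene, "somatic", "c.100del", "p.synthetic_fs1",
                       truncating = TRUE)
  if (use_loh) {
    somatic_profile(variant_table(v1), loh = "definite",
                    msings_score = msings)
  } else {
    v2 <- variant_record(gene, "somatic", "c.900dup", "p.synthetic_fs2",
                         truncating = TRUE)
    somatic_profile(variant_table(v1, v2), loh = "none",
                    msings_score = msings)
  }
}

#' Generate a synthetic screened CRC cohort
#'
#' Draws per-etiology counts (multinomial, or largest-remainder exact), then
#' builds cases whose stain, methylation, germline and somatic evidence are
#' consistent with their etiology: Lynch cases carry exactly one qualifying
#' germline mutation (pattern-concordant stains, or weak/normal stains for
#' the configured fraction of MSH6 cases and the sporadic-tumour carriers);
#' hypermethylated cases have MLH1/PMS2 loss with methylation at or above
#' threshold; double-somatic cases carry two somatic hits or one hit with
#' definite LOH; unexplained cases have abnormal stains and an uninformative
#' work-up. The same seed always yields an identical cohort.
#'
#' @param config a [cohort_config()]
#' @return list of [case_record()]s with `etiology_true` set
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases
  if (n == 0L) return(list())
  mix <- config$etiology_mix
  counts <- if (config$exact) {
    stats::setNames(.apportion(n, mix), names(mix))
  } else {
    stats::setNames(as.integer(stats::rmultinom(1, n, mix)), names(mix))
  }

  t1 <- ls_mutation_table()
  ls_pool <- t1[t1$n_crc_cohort > 0, , drop = FALSE]
  cases <- list()
  etiology <- character(0)
  cid <- 0L
  nid <- function() {
    cid <<- cid + 1L
    sprintf("S%04d", cid)
  }
  add <- function(case, et) {
    case$etiology_true <- et
    cases[[length(cases) + 1L]] <<- case
    etiology <<- c(etiology, et)
  }

  # Lynch syndrome -----------------------------------------------------------
  k_ls <- counts[["LS"]]
  if (k_ls > 0) {
    mut_idx <- if (config$exact) {
      rep(seq_len(nrow(ls_pool)), .apportion(k_ls, ls_pool$n_crc_cohort))
    } else {
      sample(seq_len(nrow(ls_pool)), k_ls, replace = TRUE,
             prob = ls_pool$n_crc_cohort)
    }
    n_sporadic <- min(config$sporadic_in_carrier_count, k_ls)
    for (i in seq_len(k_ls)) {
      m <- ls_pool[mut_idx[i], ]
      g <- variant_record(m$gene, "germline", m$hgvs_c, m$hgvs_p,
                          path_class = m$path_class,
                          truncating = m$truncating,
                          designated = m$designated)
      pattern <- switch(m$gene, MLH1 = "MLH1_PMS2", MSH2 = "MSH2_MSH6",
                        MSH6 = "MSH6_only", PMS2 = "PMS2_only")
      weak <- m$gene == "MSH6" && stats::runif(1) < config$weak_stain_rate
      sporadic <- i <= n_sporadic
      somatic <- NULL
      if (sporadic) {
        pattern <- "normal"
        weak <- FALSE
        somatic <- somatic_profile(variant_table(), loh = "none",
                                   msings_score = stats::runif(1, 0.02, 0.18))
      } else if (weak) {
        pattern <- "normal"
        somatic <- somatic_profile(
          variant_table(variant_record(m$gene, "somatic", "c.2000del",
                                       "p.synthetic_second_hit",
                                       truncating = TRUE)),
          loh = "none", msings_score = stats::runif(1, 0.25, 0.6))
      }
      meth <- if (pattern == "MLH1_PMS2") {
        call_methylation(round(stats::runif(4, 1, 8), 1))
      } else NULL
      add(case_record(nid(),
                      .ihc_for_pattern(pattern,
                                       weak_pct = if (weak) 5 else NA),
                      genotyped = TRUE, methylation = meth,
                      germline = variant_table(g), somatic = somatic), "LS")
    }
  }

  # MLH1 hypermethylation ----------------------------------------------------
  for (i in seq_len(counts[["MLH1_hm"]])) {
    m <- stats::runif(1, 20, 85)
    levels <- pmin(100, pmax(0, round(m + stats::runif(4, -5, 5), 1)))
    meth <- call_methylation(levels)
    if (meth$call != "positive") meth <- call_methylation(rep(round(m, 1), 4))
    add(case_record(nid(), .ihc_for_pattern("MLH1_PMS2"), genotyped = TRUE,
                    methylation = meth), "MLH1_hm")
  }

  # double somatic ------------------------------------------------------------
  k_ds <- counts[["double_somatic"]]
  if (k_ds > 0) {
    ds_patterns <- c(MLH1_PMS2 = 8, MSH2_MSH6 = 5, MSH6_only = 1,
                     PMS2_only = 2)
    pat <- if (config$exact) {
      rep(names(ds_patterns), .apportion(k_ds, ds_patterns))
    } else {
      sample(names(ds_patterns), k_ds, replace = TRUE, prob = ds_patterns)
    }
    for (i in seq_len(k_ds)) {
      gene <- switch(pat[i], MLH1_PMS2 = "MLH1", MSH2_MSH6 = "MSH2",
                     MSH6_only = "MSH6", PMS2_only = "PMS2")
      meth <- if (pat[i] == "MLH1_PMS2") {
        call_methylation(round(stats::runif(4, 1, 10), 1))
      } else NULL
      add(case_record(nid(), .ihc_for_pattern(pat[i]), genotyped = TRUE,
                      methylation = meth,
                      somatic = .synthetic_ds_profile(
                        gene, use_loh = i %% 2 == 0,
                        msings = stats::runif(1, 0.25, 0.6))),
          "double_somatic")
    }
  }

  # unexplained ---------------------------------------------------------------
  k_un <- counts[["unexplained"]]
  if (k_un > 0) {
    pat <- rep(c("MSH2_MSH6", "MLH1_PMS2"), .apportion(k_un, c(4, 1)))
    for (i in seq_len(k_un)) {
      if (pat[i] == "MSH2_MSH6") {
        prof <- somatic_profile(
          variant_table(variant_record("MSH2", "somatic", "c.500del",
                                       "p.synthetic_single_hit",
                                       truncating = TRUE)),
          loh = "none", msings_score = stats::runif(1, 0.25, 0.6),
          msh2_methylation = "negative")
        add(case_record(nid(), .ihc_for_pattern(pat[i]), genotyped = TRUE,
                        somatic = prof), "unexplained")
      } else {
        prof <- somatic_profile(failed = TRUE)
        add(case_record(nid(), .ihc_for_pattern(pat[i]), genotyped = TRUE,
                        methylation = call_methylation(round(
                          stats::runif(4, 1, 6), 1)),
                        somatic = prof), "unexplained")
      }
    }
  }

  # MMR proficient ------------------------------------------------------------
  k_p <- counts[["pMMR"]]
  if (k_p > 0) {
    n_geno <- if (config$exact) {
      round(k_p * config$genotyped_fraction_normal_ihc)
    } else {
      stats::rbinom(1, k_p, config$genotyped_fraction_normal_ihc)
    }
    geno <- rep(c(TRUE, FALSE), c(n_geno, k_p - n_geno))
    for (i in seq_len(k_p)) {
      add(case_record(nid(), .ihc_for_pattern("normal"),
                      genotyped = geno[i]), "pMMR")
    }
  }

  .decorate_cases(cases, etiology)
}

#' Deterministic fixture cohort reproducing the study marginals
#'
#' Reconstructs the 1,182-case screened cohort so that every published
#' marginal is met cell by cell: the stain-pattern by etiology cross-tab
#' (90/21/16/5 deficient cases across four loss patterns), the per-mutation
#' Lynch-syndrome counts, the six normal-IHC Lynch cases (three weak-stain
#' MSH6 p.Leu585Pro carriers with somatic second hits, two PMS2 frameshift
#' carriers with sporadic tumours, one carrier without tumour sequencing),
#' the 30 tumour-sequencing work-up rows as somatic profiles, 86
#' methylation-positive plus 4 BRAF-inferred hypermethylated tumours, and
#' 953 genotyped cases (all 132 abnormal-IHC plus 78.2% of normal-IHC).
#'
#' @return list of 1182 [case_record()]s
#' @export
fixture_cohort <- function() {
  t4 <- tumor_sequencing_fixture()
  t1 <- ls_mutation_table()
  cases <- list()
  etiology <- character(0)
  add <- function(case, et) {
    case$etiology_true <- et
    cases[[length(cases) + 1L]] <<- case
    etiology <<- c(etiology, et)
  }
  mut <- function(id) t1[t1$variant_id == id, ]
  germ_of <- function(id) {
    m <- mut(id)
    variant_table(variant_record(m$gene, "germline", m$hgvs_c, m$hgvs_p,
                                 path_class = m$path_class,
                                 truncating = m$truncating,
                                 designated = m$designated))
  }

  # the 30 sequenced tumours, straight from the work-up table
  t4_et <- c(double_somatic = "double_somatic",
             possibly_double_somatic = "double_somatic",
             LS = "LS", LS_sporadic_tumour = "LS",
             not_solved = "unexplained", MLH1_hm = "MLH1_hm")
  for (i in seq_len(nrow(t4))) {
    row <- t4[i, ]
    prof <- somatic_profile(row$somatic[[1]], loh = row$loh,
                            msings_score = row$msings_score,
                            msh2_methylation = row$msh2_methylation,
                            failed = row$failed)
    meth <- if (!is.na(row$meth_pct)) {
      call_methylation(rep(row$meth_pct, 4))
    } else NULL
    add(case_record(row$case_id,
                    .ihc_for_pattern(row$pattern, weak_pct = row$weak_pct),
                    genotyped = TRUE, methylation = meth,
                    braf_ihc = row$braf_ihc,
                    germline = row$germline[[1]], somatic = prof),
        unname(t4_et[row$outcome]))
  }

  # abnormal-IHC Lynch cases not in the work-up table
  ls_plan <- list(
    list(id = "PMS2_P246fs", pattern = "PMS2_only", k = 9L),
    list(id = "MSH6_L585P", pattern = "MSH6_only", k = 6L),
    list(id = "MSH6_V282fs", pattern = "MSH6_only", k = 1L),
    list(id = "MSH6_F1088fs", pattern = "MSH2_MSH6", k = 1L),
    list(id = "MSH6_R1172fs", pattern = "MSH2_MSH6", k = 1L)
  )
  fid <- 0L
  nid <- function() {
    fid <<- fid + 1L
    sprintf("F%04d", fid)
  }
  for (p in ls_plan) {
    for (i in seq_len(p$k)) {
      add(case_record(nid(), .ihc_for_pattern(p$pattern), genotyped = TRUE,
                      germline = germ_of(p$id)), "LS")
    }
  }
  # the sixth normal-IHC Lynch case: carrier without tumour sequencing
  add(case_record(nid(), .ihc_for_pattern("normal"), genotyped = TRUE,
                  germline = germ_of("PMS2_P246fs")), "LS")

  # MLH1 hypermethylation: 86 methylation-positive resections plus 3
  # biopsies with failed methylation rescued by BRAF-V600E IHC (case 240,
  # the near-threshold BRAF rescue, is already in the work-up table)
  for (i in seq_len(86L)) {
    m <- 20 + ((i * 7L) %% 61L)
    add(case_record(nid(), .ihc_for_pattern("MLH1_PMS2"), genotyped = TRUE,
                    methylation = call_methylation(c(m - 2, m + 2, m, m))),
        "MLH1_hm")
  }
  for (i in seq_len(3L)) {
    ihc <- ihc_result(c(MLH1 = "absent", PMS2 = "absent", MSH6 = "present"))
    add(case_record(nid(), ihc, specimen = "biopsy", genotyped = TRUE,
                    methylation = call_methylation(numeric(0)),
                    braf_ihc = "positive"), "MLH1_hm")
  }

  # MMR-proficient: 815 genotyped + 229 not
  for (i in seq_len(1044L)) {
    add(case_record(nid(), .ihc_for_pattern("normal"),
                    genotyped = i <= 815L), "pMMR")
  }

  .decorate_cases(cases, etiology)
}
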