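# Etiology cascade, cross-tabulation, screening metrics, proportions.

ihc_of <- function(pattern, weak_pct = NA) {
  mmrscreen:::.ihc_for_pattern(pattern, weak_pct = weak_pct)
}

test_that("cascade rules fire in the documented order", {
  # MLH1/PMS2 loss with positive methylation: sporadic hypermethylation
  hm <- case_record("a", ihc_of("MLH1_PMS2"), genotyped = TRUE,
                    methylation = call_methylation(rep(25, 4)))
  expect_equal(classify_case(hm)$label, "MLH1_hm")

  # methylation-negative MLH1/PMS2 loss with a disrupting germline
  # translocation: Lynch syndrome even though tumour sequencing exists
  trans <- case_record("b", ihc_of("MLH1_PMS2"), genotyped = TRUE,
                       methylation = call_methylation(rep(5, 4)),
                       germline = variant_table(
                         variant_record("MLH1", "germline",
                                        "t(3;5) balanced",
                                        designated = TRUE)),
                       somatic = somatic_profile(variant_table(
                         variant_record("MLH1", "somatic", "c.2041G>A",
                                        path_class = "4"))))
  expect_equal(classify_case(trans)$label, "LS")

  # isolated PMS2 loss, no germline hit, homozygous deletion with LOH
  ds <- case_record("c", ihc_of("PMS2_only"), genotyped = TRUE,
                    somatic = somatic_profile(variant_table(
                      variant_record("PMS2", "somatic",
                                     "exon 11 homozygous deletion",
                                     truncating = TRUE)), loh = "definite"))
  expect_equal(classify_case(ds)$label, "double_somatic")

  # failed methylation on a resection plus failed tumour assay: unexplained
  fail <- case_record("d", ihc_of("MLH1_PMS2"), genotyped = TRUE,
                      methylation = call_methylation(rep(2, 4)),
                      somatic = somatic_profile(failed = TRUE))
  expect_equal(classify_case(fail)$label, "unexplained")

  # evidence chains are non-empty and labels unique
  for (cs in list(hm, trans, ds, fail)) {
    call <- classify_case(cs)
    expect_length(call$label, 1)
    expect_gt(length(call$evidence_chain), 0)
  }
})

test_that("cross-tabulation conserves counts and excludes normal-IHC LS", {
  coh <- fixture_cohort()
  calls <- classify_cohort(coh)
  tab <- tabulate_etiology(calls)
  expect_equal(unlist(tab[tab$pattern == "MLH1_PMS2",
                          c("MLH1_hm", "LS", "double_somatic", "unexplained",
                            "total")], use.names = FALSE),
               c(90L, 1L, 8L, 1L, 100L))
  expect_equal(unlist(tab[tab$pattern == "Total",
                          c("MLH1_hm", "LS", "double_somatic", "unexplained",
                            "total")], use.names = FALSE),
               c(90L, 21L, 16L, 5L, 132L))
  expect_equal(attr(tab, "normal_ihc_ls"), 6L)
  # conservation: table total plus normal-pattern cases equals cohort size
  n_abnormal <- tab$total[tab$pattern == "Total"]
  expect_equal(n_abnormal + sum(!calls$pattern %in%
                                  c("MLH1_PMS2", "MSH2_MSH6", "MSH6_only",
                                    "PMS2_only")), length(coh))
})

test_that("empty cohort tabulates to zeros", {
  calls <- classify_cohort(list())
  tab <- tabulate_etiology(calls)
  expect_true(all(tab$total == 0))
  expect_equal(attr(tab, "normal_ihc_ls"), 0L)
})

test_that("classifier matches the brute-force rule-enumeration oracle", {
  for (seed in c(3, 17, 91)) {
    cfg <- cohort_config(n_cases = 50, seed = seed)
    coh <- generate_cohort(cfg)
    got <- classify_cohort(coh)$label
    want <- vapply(coh, oracle_classify, "")
    expect_equal(got, want, label = paste("seed", seed))
  }
})

test_that("perfect screen on a cohort without occult LS scores 100 everywhere", {
  cfg <- cohort_config(n_cases = 200,
                       etiology_mix = c(pMMR = 0.8, LS = 0.1, MLH1_hm = 0.1,
                                        double_somatic = 0, unexplained = 0),
                       genotyped_fraction_normal_ihc = 1,
                       weak_stain_rate = 0, sporadic_in_carrier_count = 0,
                       exact = TRUE, seed = 5)
  coh <- generate_cohort(cfg)
  calls <- classify_cohort(coh)
  perf <- screening_performance(coh, calls)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_equal(perf$ppv, 100)
  expect_equal(perf$npv, 100)
})

test_that("zero metric denominators raise a named error", {
  cfg <- cohort_config(n_cases = 20,
                       etiology_mix = c(pMMR = 1, LS = 0, MLH1_hm = 0,
                                        double_somatic = 0, unexplained = 0),
                       exact = TRUE, seed = 2)
  coh <- generate_cohort(cfg)
  calls <- classify_cohort(coh)
  expect_error(screening_performance(coh, calls), "sensitivity")
})

test_that("metrics are recomputable from the four counts", {
  coh <- fixture_cohort()
  perf <- screening_performance(coh, classify_cohort(coh))
  expect_equal(perf$tp + perf$fn, 27L)
  expect_equal(perf$tp + perf$fp + perf$tn + perf$fn, perf$n_evaluated)
  expect_equal(perf$sensitivity,
               round_half_up(100 * perf$tp / (perf$tp + perf$fn), 1))
  expect_equal(perf$npv,
               round_half_up(100 * perf$tn / (perf$tn + perf$fn), 1))
})
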