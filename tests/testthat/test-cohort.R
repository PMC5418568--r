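# Synthetic cohort generator, fixture marginals, population simulation, I/O.

test_that("fixture cohort reproduces every printed marginal", {
  coh <- fixture_cohort()
  expect_length(coh, 1182)
  calls <- classify_cohort(coh)
  patterns <- calls$pattern
  abnormal <- patterns %in% c("MLH1_PMS2", "MSH2_MSH6", "MSH6_only",
                              "PMS2_only")
  expect_equal(sum(abnormal), 132L)
  expect_equal(sum(calls$genotyped), 953L)

  # per-mutation carrier counts across the cohort
  germ <- dplyr::bind_rows(lapply(coh, function(cs) cs$germline))
  expect_equal(sum(germ$hgvs_p == "p.Leu585Pro"), 9L)
  expect_equal(sum(germ$hgvs_p == "p.Pro246Cysfs*3"), 12L)
  t1 <- ls_mutation_table()
  for (i in seq_len(nrow(t1))) {
    if (t1$n_crc_cohort[i] == 0) next
    n <- if (nzchar(t1$hgvs_p[i])) sum(germ$hgvs_p == t1$hgvs_p[i]) else
      sum(germ$hgvs_c == t1$hgvs_c[i])
    expect_equal(n, t1$n_crc_cohort[i], label = t1$variant_id[i])
  }

  # full pattern-by-etiology cross-tab
  tab <- tabulate_etiology(calls)
  expected <- rbind(c(90, 1, 8, 1, 100),
                    c(0, 2, 5, 4, 11),
                    c(0, 7, 1, 0, 8),
                    c(0, 11, 2, 0, 13),
                    c(90, 21, 16, 5, 132))
  got <- as.matrix(tab[, c("MLH1_hm", "LS", "double_somatic", "unexplained",
                           "total")])
  expect_equal(unname(got), expected)

  # etiology column totals
  grouped <- mmrscreen:::.group_label(calls$label)
  expect_equal(unname(table(grouped)[c("pMMR", "LS", "MLH1_hm",
                                       "double_somatic", "unexplained")]),
               table(factor(c(rep("a", 1044), rep("b", 27), rep("c", 90),
                              rep("d", 16), rep("e", 5)))) |> unname())
})

test_that("exact generation reproduces the configured mixture", {
  cfg <- cohort_config(exact = TRUE, seed = 99)
  coh <- generate_cohort(cfg)
  expect_length(coh, 1182)
  truth <- table(vapply(coh, function(x) x$etiology_true, ""))
  expect_equal(unname(truth[c("pMMR", "LS", "MLH1_hm", "double_somatic",
                              "unexplained")]),
               unname(table(factor(rep(1:5, c(1044, 27, 90, 16, 5))))))
  # round trip through the classifier
  grouped <- mmrscreen:::.group_label(classify_cohort(coh)$label)
  expect_equal(unname(table(grouped)[c("pMMR", "LS", "MLH1_hm",
                                       "double_somatic", "unexplained")]),
               unname(table(factor(rep(1:5, c(1044, 27, 90, 16, 5))))))
})

test_that("generator is deterministic and handles degenerate inputs", {
  a <- generate_cohort(cohort_config(n_cases = 120, seed = 7))
  b <- generate_cohort(cohort_config(n_cases = 120, seed = 7))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_length(generate_cohort(cohort_config(n_cases = 0, seed = 1)), 0)
  expect_error(cohort_config(etiology_mix = c(pMMR = 0.9, LS = 0.2,
                                              MLH1_hm = 0, double_somatic = 0,
                                              unexplained = 0)), "sum to 1")
  expect_error(cohort_config(etiology_mix = c(pMMR = 1, LS = 0)), "named")
})

test_that("every generated Lynch case carries exactly one qualifying mutation", {
  coh <- generate_cohort(cohort_config(n_cases = 400, seed = 21))
  for (cs in coh) {
    if (cs$etiology_true == "LS") {
      expect_equal(nrow(cs$germline), 1L)
      expect_true(mmrscreen:::.is_pathogenic(cs$germline))
    } else {
      expect_equal(nrow(cs$germline), 0L)
    }
    if (cs$etiology_true == "MLH1_hm") {
      expect_gte(cs$methylation$mean_level, 15)
    }
    if (!cs$genotyped) expect_equal(nrow(cs$germline), 0L)
  }
})

test_that("cohort TSV round trip preserves classification", {
  coh <- generate_cohort(cohort_config(n_cases = 150, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, length(coh))
  expect_equal(classify_cohort(back)$label, classify_cohort(coh)$label)
  # carrier counts conserve across serialization
  n_carriers <- function(x) sum(vapply(x, function(cs) nrow(cs$germline), 1L))
  expect_equal(n_carriers(back), n_carriers(coh))
  # schema version field present
  hdr <- readLines(file.path(dir, "cases.tsv"), n = 1)
  expect_match(hdr, "schema_version")
})

test_that("population generator honours the logistic effect model", {
  # null model: carrier frequency equal in cases and controls
  cfg0 <- population_config(60000, c(m1 = 0.01),
                            c(crc = 0.05), true_or = 1, seed = 3)
  pop0 <- generate_population(cfg0)
  f_case <- mean(pop0$carrier_m1[pop0$case_crc == 1])
  f_ctrl <- mean(pop0$carrier_m1[pop0$case_crc == 0])
  se <- sqrt(0.01 / sum(pop0$case_crc))
  expect_lt(abs(f_case - f_ctrl), 4 * se)

  # no carriers at frequency zero
  cfg_z <- population_config(5000, c(m1 = 0), c(crc = 0.05), 2, seed = 4)
  expect_equal(sum(generate_population(cfg_z)$carrier_m1), 0L)

  # effect model: empirical case-carrier fraction matches the closed-form
  # expectation under the logistic model
  cfg <- population_config(240000, c(m1 = 0.00234), c(crc = 0.05),
                           true_or = 3.6, seed = 8)
  pop <- generate_population(cfg)
  want <- oracle_case_carrier_fraction(0.00234, 0.05, 3.6)
  got <- mean(pop$carrier_m1[pop$case_crc == 1])
  n_case <- sum(pop$case_crc)
  expect_lt(abs(got - want), 4 * sqrt(want * (1 - want) / n_case))
})

test_that("retrospective case-control counts conserve totals", {
  set.seed(10)
  cc <- simulate_case_control(1000, 50000, 0.01, 2.5)
  expect_equal(cc$case_carrier + cc$case_noncarrier, 1000)
  expect_equal(cc$control_carrier + cc$control_noncarrier, 50000)
  expect_error(simulate_case_control(10, 10, 1.5, 2), "carrier_freq")
})

test_that("simulated translocation reads keep mate fields consistent", {
  set.seed(2)
  ra <- random_dna(3000)
  rb <- random_dna(3000)
  an <- breakpoint_anatomy("cA", 1500, "cB", 1500, dup_len = 2,
                           del_len = 3, insert_len = 6,
                           insert_revcomp = TRUE)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 10,
                                      insert_mean = 250, insert_sd = 25,
                                      read_len = 80, seed = 3)
  reads <- sim$reads
  expect_gt(nrow(reads), 0)
  by_pair <- split(seq_len(nrow(reads)), reads$qname)
  for (idx in by_pair) {
    expect_length(idx, 2)
    r1 <- reads[idx[1], ]
    r2 <- reads[idx[2], ]
    expect_equal(r1$rnext, r2$rname)
    expect_equal(r2$rnext, r1$rname)
    expect_equal(r1$pnext, r2$pos)
    expect_equal(r2$pnext, r1$pos)
  }
  # truth record carries the exact configured anatomy
  expect_equal(sim$truth$dup_len, 2L)
  expect_equal(sim$truth$del_len, 3L)
  expect_equal(sim$truth$insert_len, 6L)
  expect_true(sim$truth$insert_revcomp)

  # depth 0: truth only
  empty <- simulate_translocation_reads(ra, rb, an, depth = 0, seed = 1)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(empty$truth$bp_a, 1500L)

  # byte-identical SAM under a fixed seed
  s1 <- simulate_translocation_reads(ra, rb, an, depth = 5, seed = 9)
  s2 <- simulate_translocation_reads(ra, rb, an, depth = 5, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(s1$reads, s1$ref_lengths, f1)
  write_sam(s2$reads, s2$ref_lengths, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_translocation_reads(ra, rb, an, read_len = 500),
               "configuration error")
})
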