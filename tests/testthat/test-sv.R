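# Discordant-pair scan: region extraction, filters, clustering, anatomy.

test_that("region extraction clips at the flank boundaries", {
  reads <- dplyr::bind_rows(
    make_read("in_flank", pos = 950000L),   # gene start - 50 kb
    make_read("out_flank", pos = 850000L),  # gene start - 150 kb
    make_read("in_gene", pos = 1005000L),
    make_read("other_chr", rname = "cB", pos = 1005000L))
  gene <- list(chrom = "cA", start = 1000000L, end = 1010000L)
  got <- extract_region(reads, gene, flank = 100000L)
  expect_setequal(got$qname, c("in_flank", "in_gene"))
  body_only <- extract_region(reads, gene, flank = 0L)
  expect_setequal(body_only$qname, "in_gene")
  expect_error(extract_region(reads, list(chrom = "cZ", start = 1, end = 2)),
               "unknown chromosome")
})

test_that("quality filter drops mapq 0 and mean base quality <= 25", {
  q <- function(phred, n = 100) strrep(intToUtf8(phred + 33), n)
  reads <- dplyr::bind_rows(
    make_read("mapq0", mapq = 0L, qual = q(40)),
    make_read("q25", mapq = 60L, qual = q(25)),
    make_read("q26", mapq = 60L, qual = q(26)),
    make_read("mixed", mapq = 60L,
              qual = paste0(strrep(intToUtf8(20 + 33), 50),
                            strrep(intToUtf8(31 + 33), 50))))
  keep <- quality_keep(reads)
  expect_equal(keep, c(FALSE, FALSE, TRUE, TRUE))
  # boundary: mean exactly 25.0 is dropped, 25.1 kept
  bnd <- make_read("b", qual = paste0(strrep(intToUtf8(20 + 33), 50),
                                      strrep(intToUtf8(30 + 33), 50)))
  expect_false(quality_keep(bnd))
})

test_that("discordance reasons follow the documented order", {
  stats <- list(mean = 300, sd = 30, n_pairs = 1000)
  inter <- make_read(rnext = "cB", tlen = 0L)
  f <- is_discordant(inter, stats)
  expect_true(f)
  expect_equal(attr(f, "reason"), "mate_unaligned_or_interchrom")

  ff <- make_read(flag = 65L, pos = 100L, pnext = 400L, tlen = 400L)
  f2 <- is_discordant(ff, stats)
  expect_true(f2)
  expect_equal(attr(f2, "reason"), "orientation")

  ok <- make_read(flag = 99L, pos = 100L, pnext = 261L,
                  tlen = 360L) # mean + 2 sd: concordant
  expect_false(is_discordant(ok, stats))

  far <- make_read(flag = 99L, pos = 100L, pnext = 500L, tlen = 391L)
  f3 <- is_discordant(far, stats)
  expect_true(f3)
  expect_equal(attr(f3, "reason"), "insert_size")
})

test_that("discordance agrees with the brute-force pair oracle", {
  set.seed(31)
  ra <- random_dna(4000)
  rb <- random_dna(4000)
  an <- breakpoint_anatomy("cA", 2000, "cB", 2000, dup_len = 3,
                           del_len = 5, insert_len = 10,
                           insert_revcomp = TRUE)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 8,
                                      insert_mean = 300, insert_sd = 30,
                                      read_len = 100, seed = 14)
  reads <- utils::head(sim$reads, 1000)
  stats <- insert_stats(reads)
  got <- flag_discordant(reads, stats)$discordant
  want <- oracle_discordant(reads, stats)
  expect_equal(got, want)
  expect_gt(sum(got), 0)
})

test_that("insert-size statistics come from proper FR pairs", {
  set.seed(5)
  ra <- random_dna(5000)
  an0 <- breakpoint_anatomy("cA", 2500, "cB", 2500)
  sim <- simulate_translocation_reads(ra, random_dna(5000), an0, depth = 20,
                                      insert_mean = 320, insert_sd = 25,
                                      read_len = 100, seed = 6)
  st <- insert_stats(sim$reads)
  expect_lt(abs(st$mean - 320), 10)
  expect_lt(abs(st$sd - 25), 8)
  expect_gt(st$n_pairs, 100)
})

test_that("clustering groups by joint proximity deterministically", {
  pairify <- function(qn, pos_a, pos_b) dplyr::bind_rows(
    make_read(qn, flag = 97L, rname = "cA", pos = pos_a, rnext = "cB",
              pnext = pos_b, tlen = 0L),
    make_read(qn, flag = 145L, rname = "cB", pos = pos_b, rnext = "cA",
              pnext = pos_a, tlen = 0L))
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    pairify(sprintf("p%02d", i), 5000L + i * 30L, 8000L + i * 25L)
  }))
  cl <- cluster_discordant(reads, max_gap = 500L)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_pairs, 10L)
  expect_equal(cl[[1]]$chrom_a, "cA")

  two <- dplyr::bind_rows(pairify("a", 5000L, 8000L),
                          pairify("b", 15000L, 8000L))
  expect_length(cluster_discordant(two, max_gap = 500L), 2)
  expect_length(cluster_discordant(two[0, ], max_gap = 500L), 0)

  # input order must not matter
  shuffled <- reads[rev(seq_len(nrow(reads))), ]
  cl2 <- cluster_discordant(shuffled, max_gap = 500L)
  expect_equal(cl[[1]][c("start_a", "end_a", "start_b", "end_b",
                         "n_pairs")],
               cl2[[1]][c("start_a", "end_a", "start_b", "end_b",
                          "n_pairs")])
})

test_that("cluster filters drop masked, weak and common clusters", {
  cl <- list(chrom_a = "cA", start_a = 1000L, end_a = 1200L, chrom_b = "cB",
             start_b = 5000L, end_b = 5100L,
             qnames = sprintf("q%d", 1:36), n_pairs = 36L)
  mask_hit <- tibble::tibble(chrom = "cA", start = 1100L, end = 1500L)
  mask_miss <- tibble::tibble(chrom = "cA", start = 9000L, end = 9500L)
  expect_length(filter_clusters(list(cl), mask = mask_hit), 0)
  expect_length(filter_clusters(list(cl), mask = mask_miss), 1)
  weak <- cl
  weak$n_pairs <- 2L
  expect_length(filter_clusters(list(weak), min_support = 3L), 0)
  expect_length(filter_clusters(list(cl), control_counts = 40L,
                                n_controls = 100L,
                                max_control_fraction = 0.01), 0)
  expect_length(filter_clusters(list(cl), control_counts = 0L,
                                n_controls = 100L), 1)
})

test_that("breakpoint anatomy is recovered exactly on clean simulations", {
  set.seed(27)
  ra <- random_dna(6000)
  rb <- random_dna(5000)
  refs <- c(cA = ra, cB = rb)
  gene <- list(chrom = "cA", start = 2500, end = 3500)

  an <- breakpoint_anatomy("cA", 3000, "cB", 2500, dup_len = 3,
                           del_len = 5, insert_len = 10,
                           insert_revcomp = TRUE)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 25,
                                      insert_mean = 300, insert_sd = 30,
                                      read_len = 100, seed = 4)
  calls <- scan_translocations(sim$reads, refs, gene)
  expect_length(calls, 1)
  call <- calls[[1]]
  expect_equal(call$bp_a, 3000L)
  expect_equal(call$bp_b, 2500L)
  expect_equal(call$dup_len, 3L)
  expect_equal(call$del_len, 5L)
  expect_equal(call$insert_seq, sim$truth$insert_seq)
  expect_true(call$insert_revcomp)
  expect_gte(call$n_discordant_support, 3L)

  # blunt junction: no micro events
  blunt <- breakpoint_anatomy("cA", 3000, "cB", 2500)
  sim0 <- simulate_translocation_reads(ra, rb, blunt, depth = 25,
                                       insert_mean = 300, insert_sd = 30,
                                       read_len = 100, seed = 8)
  c0 <- scan_translocations(sim0$reads, refs, gene)[[1]]
  expect_equal(c0$dup_len, 0L)
  expect_equal(c0$del_len, 0L)
  expect_equal(c0$insert_seq, "")
})

test_that("a single spanning read localises the junction like thirty", {
  set.seed(33)
  ra <- random_dna(6000)
  rb <- random_dna(5000)
  refs <- c(cA = ra, cB = rb)
  an <- breakpoint_anatomy("cA", 3000, "cB", 2500, dup_len = 3,
                           del_len = 5, insert_len = 10,
                           insert_revcomp = TRUE)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 30,
                                      insert_mean = 300, insert_sd = 30,
                                      read_len = 100, seed = 15)
  kept <- quality_filter(sim$reads)
  st <- insert_stats(kept)
  disc <- kept[flag_discordant(kept, st)$discordant, ]
  cl <- cluster_discordant(disc)[[1]]
  full <- infer_breakpoint(cl, kept, refs)

  # keep exactly one spanning soft-clipped read per side and direction
  lead <- mmrscreen:::.cigar_clip(kept$cigar, "left")
  trail <- mmrscreen:::.cigar_clip(kept$cigar, "right")
  sc <- lead > 0 | trail > 0
  pick <- !duplicated(paste(kept$rname, lead > 0, trail > 0)) & sc
  thin <- kept[!sc | pick, ]
  one <- infer_breakpoint(cl, thin, refs)
  expect_equal(one$bp_a, full$bp_a)
  expect_equal(one$bp_b, full$bp_b)
  expect_equal(one$dup_len, full$dup_len)
  expect_equal(one$del_len, full$del_len)
})

test_that("concordant background never creates or changes a call", {
  set.seed(44)
  ra <- random_dna(5000)
  rb <- random_dna(5000)
  refs <- c(cA = ra, cB = rb)
  gene <- list(chrom = "cA", start = 2000, end = 3000)
  an <- breakpoint_anatomy("cA", 2500, "cB", 2500, dup_len = 3,
                           del_len = 5, insert_len = 10,
                           insert_revcomp = TRUE)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 25,
                                      insert_mean = 300, insert_sd = 30,
                                      read_len = 100, seed = 16)
  base_call <- scan_translocations(sim$reads, refs, gene)[[1]]
  # double the concordant background
  extra <- simulate_translocation_reads(ra, rb, an, depth = 25,
                                        insert_mean = 300, insert_sd = 30,
                                        read_len = 100, seed = 17)
  bg <- extra$reads[grepl("^n", extra$reads$qname), ]
  bg$qname <- paste0("x", bg$qname)
  more <- scan_translocations(dplyr::bind_rows(sim$reads, bg), refs, gene)
  expect_length(more, 1)
  expect_equal(more[[1]]$bp_a, base_call$bp_a)
  expect_equal(more[[1]]$bp_b, base_call$bp_b)
  expect_equal(more[[1]]$dup_len, base_call$dup_len)

  # removing the cluster's reads below min_support removes the call
  der <- sim$reads[grepl("^d", sim$reads$qname), ]
  keep_names <- unique(der$qname)[1:2]
  thin <- dplyr::bind_rows(sim$reads[grepl("^n", sim$reads$qname), ],
                           der[der$qname %in% keep_names, ])
  expect_length(scan_translocations(thin, refs, gene, min_support = 3L), 0)
})

test_that("SAM round trip through the standard reader is faithful", {
  set.seed(50)
  ra <- random_dna(3000)
  rb <- random_dna(3000)
  an <- breakpoint_anatomy("cA", 1500, "cB", 1500, dup_len = 1,
                           del_len = 2, insert_len = 4)
  sim <- simulate_translocation_reads(ra, rb, an, depth = 8,
                                      insert_mean = 250, insert_sd = 20,
                                      read_len = 80, seed = 18)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads, sim$ref_lengths, f)
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(sim$reads))
  ord1 <- order(sim$reads$qname, sim$reads$flag)
  ord2 <- order(back$qname, back$flag)
  for (col in c("qname", "flag", "rname", "pos", "cigar", "pnext", "tlen",
                "seq")) {
    expect_equal(back[[col]][ord2], sim$reads[[col]][ord1], label = col)
  }
  calls <- scan_translocations(back, c(cA = ra, cB = rb),
                               list(chrom = "cA", start = 1000, end = 2000))
  expect_length(calls, 1)
  expect_equal(calls[[1]]$bp_a, 1500L)
})
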