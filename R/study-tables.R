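# Published study constants used by the fixture cohort, the simulators and
# the association defaults. These are inputs to the pipeline (printed tables
# are data), not results computed by it.

#' Founder and private Lynch-syndrome mutations
#'
#' The Lynch-syndrome mutations identified in the population, with their
#' pathogenicity class, the number of carriers in the screened CRC cohort,
#' and the population carrier frequency where the mutation is imputable.
#' `designated` marks variants established as pathogenic by study-level
#' evidence (tumour second hits, karyotype confirmation) despite a class-3
#' or unknown database classification.
#'
#' @return tibble, one row per mutation
#' @export
ls_mutation_table <- function() {
  tibble::tibble(
    variant_id = c("PMS2_P246fs", "PMS2_M1", "MSH6_L585P", "MLH1_translocation",
                   "MSH6_V282fs", "MSH6_F1088fs", "MSH6_R1172fs", "MSH2_Y815X",
                   "PMS2_N71fs", "PMS2_E705K"),
    gene = c("PMS2", "PMS2", "MSH6", "MLH1", "MSH6", "MSH6", "MSH6", "MSH2",
             "PMS2", "PMS2"),
    hgvs_c = c("c.736_741del6ins11", "c.2T>A", "c.1754T>C", "t(3;5) balanced",
               "c.843_844insAC", "c.3261dupC", "c.3514dupA", "c.2445T>A",
               "c.211_214del", "c.2113G>A"),
    hgvs_p = c("p.Pro246Cysfs*3", "p.Met1?", "p.Leu585Pro", "",
               "p.Val282Thrfs*10", "p.Phe1088Leufs*5", "p.Arg1172Lysfs*5",
               "p.Tyr815*", "p.Asn71Aspfs*4", "p.Glu705Lys"),
    path_class = c("5", "NK", "3", "NK", "NK", "5", "5", "NK", "NK", "3"),
    truncating = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE),
    designated = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE),
    n_crc_cohort = c(12L, 0L, 9L, 1L, 1L, 1L, 1L, 0L, 1L, 1L),
    carrier_freq = c(0.00234, 0.00092, 0.00080, NA, NA, NA, NA, NA, NA, NA)
  )
}

#' Population carrier frequencies of the imputable founder mutations
#'
#' @return named numeric vector of carrier fractions
#' @export
founder_carrier_freqs <- function() {
  t1 <- ls_mutation_table()
  stats::setNames(t1$carrier_freq, t1$variant_id)[!is.na(t1$carrier_freq)]
}

#' Founder-mutation odds ratios by cancer type
#'
#' Per-variant, per-cancer association summaries for the three imputable
#' founder mutations: odds ratio, 95% confidence interval, p-value, the
#' case/control totals behind each fit, imputation quality (`info`,
#' pass-through metadata) and the published lifetime-risk conversions by
#' sex. Used as the simulation configuration for parameter-recovery checks
#' and as the input to [risk_from_or()] workflows.
#'
#' @return tibble, one row per variant x cancer
#' @export
founder_or_table <- function() {
  tibble::tibble(
    variant_id = rep(c("MSH6_L585P", "PMS2_P246fs", "PMS2_M1"), each = 5L),
    carrier_freq = rep(c(0.00080, 0.00234, 0.00092), each = 5L),
    cancer = c("endometrial", "colorectal", "colon", "rectal", "brain",
               "endometrial", "colorectal", "colon", "rectal", "ovarian",
               "endometrial", "colorectal", "colon", "rectal", "ovarian"),
    odds_ratio = c(32.8, 10.1, 7.5, 12.4, 8.9,
                   9.9, 3.6, 3.8, 2.3, 3.9,
                   7.5, 2.2, 2.7, 0.9, 6.6),
    ci_low  = c(13.5, 5.1, 3.3, 4.4, 2.2, 4.9, 2.2, 2.2, 0.8, 1.3,
                2.4, 0.94, 1.1, 0.13, 1.8),
    ci_high = c(80.0, 20.1, 17.0, 34.8, 36.2, 19.8, 5.9, 6.6, 6.9, 11.9,
                23.5, 5.3, 6.8, 6.7, 24.3),
    p_value = c(1.61e-14, 4.19e-11, 1.89e-6, 1.79e-6, 2.19e-3,
                1.30e-10, 7.64e-7, 1.7e-7, 1.2e-1, 1.53e-2,
                5.53e-4, 7.01e-2, 3.7e-2, 5.4e-1, 4.16e-3),
    n_cases = c(923L, 3834L, 2793L, 1082L, 702L,
                923L, 3834L, 2793L, 1082L, 779L,
                923L, 3834L, 2793L, 1082L, 779L),
    n_controls = c(115104L, 262425L, 263466L, 260587L, 358789L,
                   115104L, 262425L, 263466L, 260587L, 121299L,
                   115104L, 262425L, 263466L, 260587L, 121299L),
    info = c(0.92, NA, NA, NA, NA, 0.99, NA, NA, NA, NA, 0.99, NA, NA, NA, NA),
    risk_male = c(NA, 0.364, 0.179, 0.161, 0.134,
                  NA, 0.129, 0.092, 0.030, NA,
                  NA, 0.080, 0.064, 0.012, NA),
    risk_female = c(0.492, 0.253, 0.127, 0.099, 0.107,
                    0.148, 0.090, 0.065, 0.019, 0.035,
                    0.113, 0.055, 0.046, 0.008, 0.060)
  )
}

# variant-record shorthand for the tumour-sequencing table
.v <- function(gene, hgvs_c = "", hgvs_p = "", origin = "somatic",
               cls = "NK", tr = FALSE, des = FALSE) {
  variant_record(gene, origin, hgvs_c, hgvs_p, path_class = cls,
                 truncating = tr, designated = des)
}

# The 30 tumour-sequencing work-up rows: instability score, methylation,
# stain pattern, mutation/LOH evidence and the adjudicated outcome. meth_pct
# NA means not tested; weak_pct annotates weak-but-present MSH6 stains.
.table4_rows <- function() {
  fs <- function(g, c, p) .v(g, c, p, tr = TRUE)
  r <- function(id, msings, msi, meth, pattern, somatic, germline, loh,
                outcome, weak_pct = NA, msh2_meth = "not_done",
                failed = FALSE, braf = "not_done") {
    list(id = id, msings = msings, msi = msi, meth_pct = as.numeric(meth),
         pattern = pattern, somatic = somatic, germline = germline,
         loh = loh, outcome = outcome, weak_pct = as.numeric(weak_pct),
         msh2_meth = msh2_meth, failed = failed, braf = braf)
  }
  g_l585p <- .v("MSH6", "c.1754T>C", "p.Leu585Pro", "germline", "3",
                des = TRUE)
  g_pms2fs <- fs("PMS2", "c.736_741del6ins11", "p.Pro246Cysfs*3")
  g_pms2fs$origin <- "germline"
  list(
    r("197", 0.4062, "MSI_H", 10, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.493del", "p.A165Lfs*2")),
      variant_table(), "definite", "double_somatic"),
    r("237", 0.4531, "MSI_H", 4, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.2237del", "p.L746Rfs*37")),
      variant_table(), "definite", "double_somatic"),
    r("466", 0.5538, "MSI_H", 5, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.1684C>T", "p.Q562*")),
      variant_table(), "definite", "double_somatic"),
    r("506", 0.5079, "MSI_H", 4, "MLH1_PMS2",
      variant_table(.v("MLH1", "c.199G>A", "p.G67R", cls = "4")),
      variant_table(), "definite", "double_somatic"),
    r("745", 0.4923, "MSI_H", 10, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.1783_1784del", "p.S595Wfs*14")),
      variant_table(), "definite", "double_somatic"),
    r("985", 0.4462, "MSI_H", 10, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.588del", "p.K196Nfs*6"),
                    fs("MLH1", "c.171del", "p.K57Nfs*2"),
                    .v("MLH1", "c.299G>A", "p.R100Q")),
      variant_table(), "none", "double_somatic"),
    r("1034", 0.5538, "MSI_H", 6, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.2142G>A", "p.W714*"),
                    fs("MLH1", "c.670_673dup", "p.R226*")),
      variant_table(), "none", "double_somatic"),
    r("1141", 0.4923, "MSI_H", NA, "MLH1_PMS2",
      variant_table(fs("MLH1", "c.2206G>T", "p.E736*")),
      variant_table(), "definite", "double_somatic"),
    r("246", 0.4769, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.545_552del", "p.D182Vfs*4"),
                    fs("MSH2", "c.1661+1G>A", "splicing")),
      variant_table(), "none", "double_somatic"),
    r("1082", 0.3492, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.82del", "p.E28Rfs*36"),
                    fs("MSH2", "c.1310del", "p.V437Gfs*17")),
      variant_table(), "none", "double_somatic"),
    r("1049", 0.4754, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.942+3A>T", "splicing")),
      variant_table(), "definite", "double_somatic"),
    r("959", 0.5846, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.2459-2A>C", "splicing"),
                    fs("MSH2", "c.2352del", "p.H785Mfs*27")),
      variant_table(), "none", "double_somatic"),
    r("951", 0.5156, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.425C>G", "p.S142*"),
                    fs("MSH2", "c.942+3A>T", "splicing")),
      variant_table(), "none", "double_somatic"),
    r("509", 0.1587, "MSS", NA, "MSH6_only",
      variant_table(fs("MSH2", "inversion", "")),
      variant_table(.v("MSH2", "c.2210+7G>T", "splice region", "germline")),
      "maybe", "possibly_double_somatic"),
    r("1231", 0.4462, "MSI_H", NA, "PMS2_only",
      variant_table(fs("PMS2", "c.325delG", "p.E109Kfs*3"),
                    fs("PMS2", "c.444delC", "p.Y149Tfs*52")),
      variant_table(), "none", "double_somatic"),
    r("1022", 0.2857, "MSI_H", NA, "PMS2_only",
      variant_table(fs("PMS2", "exon 11 homozygous deletion", "")),
      variant_table(), "definite", "double_somatic"),
    r("427", 0.4462, "MSI_H", NA, "PMS2_only",
      variant_table(),
      variant_table(.v("PMS2", "c.2113G>A", "p.Glu705Lys", "germline", "3",
                       des = TRUE)),
      "likely", "LS"),
    r("1057", 0.5692, "MSI_H", NA, "PMS2_only",
      variant_table(.v("PMS2", "c.2113G>A", "p.E705K", cls = "3",
                       des = TRUE)),
      variant_table(.v("PMS2", "c.211_214del", "p.Asn71Aspfs*4", "germline",
                       tr = TRUE)),
      "maybe", "LS"),
    r("339", 0.5626, "MSI_H", 5, "MLH1_PMS2",
      variant_table(.v("MLH1", "c.2041G>A", "p.Ala681Thr", cls = "4")),
      variant_table(.v("MLH1", "t(3;5) balanced", "", "germline",
                       des = TRUE)),
      "none", "LS"),
    r("786", 0.2787, "MSI_H", NA, "normal",
      variant_table(fs("MSH6", "c.3509delT", "p.I1170Mfs*14")),
      variant_table(g_l585p), "none", "LS", weak_pct = 3),
    r("30", 0.1228, "MSS", NA, "normal",
      variant_table(fs("MSH6", "c.3261del", "p.F1088Serfs*2")),
      variant_table(g_l585p), "none", "LS", weak_pct = 5),
    r("94", 0.4032, "MSI_H", NA, "normal",
      variant_table(.v("MSH6", "c.3016T>G", "p.Y1006D", cls = "4")),
      variant_table(g_l585p), "none", "LS", weak_pct = 25),
    r("1250", 0.1538, "MSS", NA, "normal",
      variant_table(), variant_table(g_pms2fs), "none",
      "LS_sporadic_tumour"),
    r("873", 0.0615, "MSS", NA, "normal",
      variant_table(), variant_table(g_pms2fs), "none",
      "LS_sporadic_tumour"),
    r("162", 0.5385, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.2458+2delT", "splicing")),
      variant_table(), "none", "not_solved", msh2_meth = "negative"),
    r("1127", 0.2188, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.943-1G>C", "splicing")),
      variant_table(), "none", "not_solved", msh2_meth = "negative"),
    r("1108", 0.4154, "MSI_H", NA, "MSH2_MSH6",
      variant_table(fs("MSH2", "c.2131C>T", "p.R711*")),
      variant_table(.v("MSH2", "c.2635-10T>G", "splice region", "germline")),
      "none", "not_solved", msh2_meth = "negative"),
    r("418", 0.1077, "MSS", NA, "MSH2_MSH6",
      variant_table(.v("MSH2", "c.1077-2736T>G", "deep intronic")),
      variant_table(), "definite", "not_solved"),
    r("827", 0.0923, "MSS", 2, "MLH1_PMS2",
      variant_table(), variant_table(), "none", "not_solved", failed = TRUE),
    r("240", 0.2742, "MSI_H", 14, "MLH1_PMS2",
      variant_table(), variant_table(), "none", "MLH1_hm",
      braf = "positive")
  )
}

#' Tumour-sequencing work-up fixture
#'
#' The 30 ColoSeq-tested cases as a tibble: instability score, printed MSI
#' label, MLH1 methylation percentage (NA when not tested), IHC loss
#' pattern, somatic and germline variant evidence (list columns), LOH grade
#' and the adjudicated outcome. These rows double as the somatic profiles of
#' the corresponding fixture-cohort cases.
#'
#' @return tibble with one row per sequenced tumour
#' @export
tumor_sequencing_fixture <- function() {
  rows <- .table4_rows()
  tibble::tibble(
    case_id = vapply(rows, `[[`, "", "id"),
    msings_score = vapply(rows, `[[`, 0, "msings"),
    msi_printed = vapply(rows, `[[`, "", "msi"),
    meth_pct = vapply(rows, `[[`, 0, "meth_pct"),
    pattern = vapply(rows, `[[`, "", "pattern"),
    weak_pct = vapply(rows, `[[`, 0, "weak_pct"),
    somatic = lapply(rows, `[[`, "somatic"),
    germline = lapply(rows, `[[`, "germline"),
    loh = vapply(rows, `[[`, "", "loh"),
    msh2_methylation = vapply(rows, `[[`, "", "msh2_meth"),
    failed = vapply(rows, `[[`, TRUE, "failed"),
    braf_ihc = vapply(rows, `[[`, "", "braf"),
    outcome = vapply(rows, `[[`, "", "outcome")
  )
}

# Table-2-style per-etiology descriptive distributions (ages as
# median/quartiles, categorical probabilities). Used only to decorate
# generated cases; the classifier never reads them.
.demography_defaults <- function() {
  list(
    pMMR = list(age = c(61, 71, 78), male = 0.576,
                stage = c(I = 193, II = 282, III = 298, IV = 230, unknown = 41),
                loc = c(right = 357, left = 366, rectum = 307)),
    LS = list(age = c(55, 62, 72), male = 0.815,
              stage = c(I = 5, II = 16, III = 4, IV = 2, unknown = 0),
              loc = c(right = 14, left = 9, rectum = 4)),
    MLH1_hm = list(age = c(73, 78, 84), male = 0.278,
                   stage = c(I = 9, II = 47, III = 24, IV = 6, unknown = 4),
                   loc = c(right = 76, left = 8, rectum = 4)),
    double_somatic = list(age = c(57, 69, 79), male = 0.563,
                          stage = c(I = 1, II = 9, III = 4, IV = 1, unknown = 1),
                          loc = c(right = 13, left = 2, rectum = 1)),
    unexplained = list(age = c(35, 75, 86), male = 0.4,
                       stage = c(I = 3, II = 2, III = 0, IV = 0, unknown = 0),
                       loc = c(right = 2, left = 1, rectum = 2))
  )
}
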