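# Cohort TSV I/O: one row per case, with a VCF-like variant sidecar keyed
# by case id.

#' Write a cohort to TSV
#'
#' Emits `cases.tsv` (one row per case; stains, methylation levels and
#' somatic-profile scalars as flat columns, a `schema_version` field first)
#' and `variants.tsv` (one row per germline or somatic variant, keyed by
#' `case_id`).
#'
#' @param cohort list of [case_record()]s
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cases <- lapply(cohort, function(cs) {
    s <- cs$ihc$stains
    p <- cs$ihc$percent_positive
    som <- cs$somatic
    tibble::tibble(
      schema_version = 1L, case_id = cs$case_id,
      etiology_true = cs$etiology_true, sex = cs$sex, age_dx = cs$age_dx,
      location = cs$location, stage = cs$stage, specimen = cs$specimen,
      genotyped = cs$genotyped,
      stain_MLH1 = s[["MLH1"]], stain_MSH2 = s[["MSH2"]],
      stain_MSH6 = s[["MSH6"]], stain_PMS2 = s[["PMS2"]],
      pct_MLH1 = p[["MLH1"]], pct_MSH2 = p[["MSH2"]],
      pct_MSH6 = p[["MSH6"]], pct_PMS2 = p[["PMS2"]],
      meth_tested = !is.null(cs$methylation),
      meth_levels = if (is.null(cs$methylation)) "" else
        paste(cs$methylation$cpg_levels, collapse = ";"),
      braf_ihc = cs$braf_ihc,
      som_present = !is.null(som),
      som_loh = if (is.null(som)) "" else som$loh,
      som_msings = if (is.null(som)) NA_real_ else som$msings_score,
      som_msh2_meth = if (is.null(som)) "" else som$msh2_methylation,
      som_failed = if (is.null(som)) NA else som$failed)
  })
  cases <- dplyr::bind_rows(cases)
  vars <- lapply(cohort, function(cs) {
    v <- dplyr::bind_rows(
      cs$germline,
      if (!is.null(cs$somatic)) cs$somatic$variants else NULL)
    if (!nrow(v)) return(NULL)
    v$case_id <- cs$case_id
    v$schema_version <- 1L
    v[, c("schema_version", "case_id", "origin", "gene", "hgvs_c", "hgvs_p",
          "path_class", "truncating", "designated", "vaf")]
  })
  vars <- dplyr::bind_rows(vars)
  utils::write.table(cases, file.path(dir, "cases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(vars, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `cases.tsv` and `variants.tsv`
#' @return list of [case_record()]s
#' @export
read_cohort <- function(dir) {
  cases <- utils::read.delim(file.path(dir, "cases.tsv"),
                             colClasses = c(meth_levels = "character"))
  vpath <- file.path(dir, "variants.tsv")
  vars <- if (file.exists(vpath) && file.size(vpath) > 0) {
    utils::read.delim(vpath)
  } else NULL
  lapply(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    stains <- c(MLH1 = row$stain_MLH1, MSH2 = row$stain_MSH2,
                MSH6 = row$stain_MSH6, PMS2 = row$stain_PMS2)
    pct <- c(MLH1 = row$pct_MLH1, MSH2 = row$pct_MSH2, MSH6 = row$pct_MSH6,
             PMS2 = row$pct_PMS2)
    ihc <- ihc_result(stains, percent_positive = pct[!is.na(pct)])
    meth <- if (isTRUE(row$meth_tested)) {
      lv <- row$meth_levels
      call_methylation(if (nchar(lv)) as.numeric(strsplit(lv, ";")[[1]])
                       else numeric(0))
    } else NULL
    cv <- if (!is.null(vars)) vars[vars$case_id == row$case_id, , drop = FALSE]
      else NULL
    mk <- function(origin) {
      if (is.null(cv) || !nrow(cv)) return(variant_table())
      sel <- cv[cv$origin == origin, , drop = FALSE]
      if (!nrow(sel)) return(variant_table())
      do.call(variant_table, lapply(seq_len(nrow(sel)), function(j) {
        variant_record(sel$gene[j], origin, sel$hgvs_c[j], sel$hgvs_p[j],
                       path_class = as.character(sel$path_class[j]),
                       truncating = sel$truncating[j],
                       designated = sel$designated[j], vaf = sel$vaf[j])
      }))
    }
    som <- if (isTRUE(row$som_present)) {
      somatic_profile(mk("somatic"), loh = row$som_loh,
                      msings_score = row$som_msings,
                      msh2_methylation = row$som_msh2_meth,
                      failed = isTRUE(row$som_failed))
    } else NULL
    case_record(row$case_id, ihc, sex = row$sex, age_dx = row$age_dx,
                location = row$location, stage = row$stage,
                specimen = row$specimen, genotyped = isTRUE(row$genotyped),
                methylation = meth, braf_ihc = row$braf_ihc,
                germline = if (isTRUE(row$genotyped)) mk("germline") else
                  variant_table(),
                somatic = som, etiology_true = row$etiology_true)
  })
}
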