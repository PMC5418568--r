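# Tumour-sequencing interpretation: MSI calling, LOH banding, and the
# double-somatic "solved" rules.

#' Construct an MMR variant record
#'
#' @param gene one of MLH1, MSH2, MSH6, PMS2, EPCAM
#' @param origin `"germline"` or `"somatic"`
#' @param hgvs_c,hgvs_p HGVS descriptions (free text, may be empty)
#' @param path_class pathogenicity class `"1"`–`"5"` or `"NK"` (not known)
#' @param truncating logical; frameshift/nonsense/canonical-splice variants
#'   predicted to truncate the protein count as pathogenic regardless of
#'   class
#' @param designated logical; variant designated pathogenic by study-level
#'   evidence (for example a karyotype-confirmed disrupting translocation or
#'   a class-3 variant with demonstrated somatic second hits)
#' @param vaf somatic variant allele fraction in \[0, 1\], if measured
#' @return one-row tibble
#' @export
variant_record <- function(gene, origin, hgvs_c = "", hgvs_p = "",
                           path_class = "NK", truncating = FALSE,
                           designated = FALSE, vaf = NA_real_) {
  gene <- .match_one(gene, .mmr_genes_ep, "gene")
  origin <- .match_one(origin, c("germline", "somatic"), "origin")
  path_class <- .match_one(as.character(path_class),
                           c("1", "2", "3", "4", "5", "NK"), "path_class")
  tibble::tibble(gene = gene, origin = origin, hgvs_c = hgvs_c,
                 hgvs_p = hgvs_p, path_class = path_class,
                 truncating = isTRUE(truncating),
                 designated = isTRUE(designated), vaf = as.numeric(vaf))
}

#' @rdname variant_record
#' @param ... variant records to combine
#' @export
variant_table <- function(...) {
  recs <- list(...)
  if (!length(recs)) {
    return(variant_record("MLH1", "somatic")[0, ])
  }
  dplyr::bind_rows(recs)
}

# pathogenic or likely pathogenic: class 4/5, predicted truncation, or
# designated by study-level evidence
.is_pathogenic <- function(v) {
  v$path_class %in% c("4", "5") | v$truncating | v$designated
}

#' Construct a somatic tumour-sequencing profile
#'
#' @param variants tibble of somatic [variant_record()]s (germline variants
#'   re-identified by the tumour assay may be included with
#'   `origin = "germline"`)
#' @param loh loss-of-heterozygosity grade: `none`, `maybe`, `likely` or
#'   `definite`
#' @param msings_score fraction of unstable microsatellite loci in \[0, 1\]
#' @param msh2_methylation `positive`, `negative` or `not_done`
#' @param failed logical; `TRUE` when the assay was indeterminate (for
#'   example low tumour DNA content)
#' @param msi_threshold threshold passed to [call_msi()]
#' @return a `somatic_profile` list; `msi_call` is derived from the score
#' @export
somatic_profile <- function(variants = variant_table(), loh = "none",
                            msings_score = NA_real_,
                            msh2_methylation = "not_done", failed = FALSE,
                            msi_threshold = 0.2) {
  loh <- .match_one(loh, c("none", "maybe", "likely", "definite"), "loh")
  msh2_methylation <- .match_one(msh2_methylation,
                                 c("positive", "negative", "not_done"),
                                 "msh2_methylation")
  msi <- if (is.na(msings_score)) NA_character_ else
    call_msi(msings_score, msi_threshold)
  structure(list(variants = variants, loh = loh,
                 msings_score = msings_score, msi_call = msi,
                 msh2_methylation = msh2_methylation, failed = isTRUE(failed)),
            class = "somatic_profile")
}

#' Call microsatellite instability from an instability score
#'
#' The score is the fraction of assayed microsatellite loci that are
#' unstable in tumour sequencing data. The call is MSI-high at or above the
#' threshold (default 0.2, the published convention for this score type),
#' inclusive at the boundary.
#'
#' @param msings_score fraction in \[0, 1\]
#' @param threshold MSI-high cut-off (default 0.2)
#' @return `"MSI_H"` or `"MSS"`
#' @export
call_msi <- function(msings_score, threshold = 0.2) {
  .check_fraction(msings_score, "msings_score")
  ifelse(msings_score >= threshold, "MSI_H", "MSS")
}

#' Grade loss of heterozygosity from a variant allele fraction
#'
#' For a germline heterozygous variant in a tumour that has lost the
#' wild-type allele, every cell contributes one variant allele while only
#' the normal-cell fraction contributes reference alleles, so the expected
#' VAF is `1 / (2 - purity)`. The observed/expected ratio is banded into
#' `definite`/`likely`/`maybe`/`none`; a balanced heterozygous VAF of 0.5 at
#' full purity gives a ratio of 0.5 and falls below every band.
#'
#' @param variant_vaf observed variant allele fraction in \[0, 1\]
#' @param purity tumour cell fraction in (0, 1\]
#' @param bands named vector of observed/expected ratio cut-offs (defaults
#'   `definite >= 0.95`, `likely >= 0.85`, `maybe >= 0.60`)
#' @return LOH grade: `none`, `maybe`, `likely` or `definite`
#' @export
infer_loh <- function(variant_vaf, purity,
                      bands = c(definite = 0.95, likely = 0.85, maybe = 0.60)) {
  .check_fraction(variant_vaf, "variant_vaf")
  .check_fraction(purity, "purity")
  if (purity == 0) stop("LOH is undefined at purity 0", call. = FALSE)
  expected <- 1 / (2 - purity)
  ratio <- variant_vaf / expected
  if (ratio >= bands[["definite"]]) "definite"
  else if (ratio >= bands[["likely"]]) "likely"
  else if (ratio >= bands[["maybe"]]) "maybe"
  else "none"
}

.loh_rank <- function(loh) {
  match(loh, c("none", "maybe", "likely", "definite")) - 1L
}

#' Resolve a tumour profile against germline findings
#'
#' Applies the solved/possibly-solved rules for mismatch-repair deficient
#' tumours. With a qualifying germline mutation the question is whether the
#' tumour shows a second hit in the same gene (a somatic mutation, or LOH
#' graded at least `likely`): with one, the tumour is attributed to Lynch
#' syndrome; without, the carrier developed a sporadic tumour. Without a
#' qualifying germline mutation the tumour is solved as double somatic when
#' one gene carries two pathogenic/likely-pathogenic somatic hits, or one
#' such hit plus LOH graded at least `likely`; one hit with `maybe` LOH is
#' only possibly solved; anything less is unsolved.
#'
#' A class-3 germline variant qualifies as the germline hit only when the
#' tumour shows a somatic second hit in its gene — the configuration that
#' justifies upgrading such a variant to pathogenic.
#'
#' @param profile a [somatic_profile()] (or `NULL` when tumour sequencing
#'   was not performed/failed)
#' @param germline tibble of germline [variant_record()]s
#' @return one of `solved_double_somatic`, `possibly_double_somatic`,
#'   `lynch_second_hit`, `lynch_sporadic_tumour`, `not_solved`
#' @export
resolve_double_somatic <- function(profile, germline = variant_table()) {
  if (is.null(profile) || profile$failed) return("not_solved")
  stopifnot(inherits(profile, "somatic_profile"))
  som <- profile$variants[profile$variants$origin == "somatic", , drop = FALSE]
  loh_hit <- .loh_rank(profile$loh) >= .loh_rank("likely")
  loh_maybe <- profile$loh == "maybe"

  if (nrow(germline)) {
    g_direct <- germline[.is_pathogenic(germline), , drop = FALSE]
    # class-3 escalation: qualifies only in the presence of a somatic second
    # hit (any somatic variant in the gene, or at least likely LOH)
    g3 <- germline[germline$path_class == "3" & !.is_pathogenic(germline), ,
                   drop = FALSE]
    g3 <- g3[vapply(g3$gene, function(g) {
      any(som$gene == g) || loh_hit
    }, logical(1)), , drop = FALSE]
    g_qual <- dplyr::bind_rows(g_direct, g3)
    if (nrow(g_qual)) {
      second <- vapply(g_qual$gene, function(g) {
        any(som$gene == g) || loh_hit
      }, logical(1))
      return(if (any(second)) "lynch_second_hit" else "lynch_sporadic_tumour")
    }
  }

  if (nrow(som)) {
    hits <- som[.is_pathogenic(som), , drop = FALSE]
    if (nrow(hits)) {
      per_gene <- table(hits$gene)
      if (max(per_gene) >= 2L) return("solved_double_somatic")
      if (loh_hit) return("solved_double_somatic")
      if (loh_maybe) return("possibly_double_somatic")
    }
  }
  "not_solved"
}
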