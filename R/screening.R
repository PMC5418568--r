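# IHC panel logic, MLH1 promoter-methylation calling, BRAF-V600E reflex.

#' Construct an IHC result
#'
#' Stain calls for the four MMR proteins. A weak-but-present stain must be
#' accompanied by a percent-positive annotation above 1% (weak stains below
#' that are scored absent at the bench and should be recorded as such); a
#' stain whose internal control failed carries no information and is coerced
#' to `not_done`.
#'
#' @param stains named character vector over a subset of MLH1, MSH2, MSH6,
#'   PMS2 with values `present`, `absent`, `weak_present` or `not_done`;
#'   proteins not named are `not_done`.
#' @param percent_positive optional named numeric vector, percent of tumour
#'   cells staining, for the proteins it annotates.
#' @param internal_control optional named logical vector; `FALSE` marks a
#'   failed internal control.
#' @return an `ihc_result` list with elements `stains` and
#'   `percent_positive`.
#' @export
ihc_result <- function(stains, percent_positive = NULL, internal_control = NULL) {
  full <- stats::setNames(rep("not_done", 4L), .mmr_genes)
  if (length(stains)) {
    bad <- setdiff(names(stains), .mmr_genes)
    if (length(bad)) stop("unknown MMR protein(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    vals <- match.arg(unname(stains),
                      c("present", "absent", "weak_present", "not_done"),
                      several.ok = TRUE)
    full[names(stains)] <- vals
  }
  if (!is.null(internal_control)) {
    failed <- names(internal_control)[!internal_control]
    full[intersect(failed, names(full))] <- "not_done"
  }
  pct <- stats::setNames(rep(NA_real_, 4L), .mmr_genes)
  if (!is.null(percent_positive)) {
    pct[names(percent_positive)] <- as.numeric(percent_positive)
  }
  weak <- names(full)[full == "weak_present"]
  if (any(is.na(pct[weak]) | pct[weak] <= 1)) {
    stop("weak_present stains require percent_positive_cells > 1%",
         call. = FALSE)
  }
  structure(list(stains = full, percent_positive = pct), class = "ihc_result")
}

#' Select the IHC staining panel
#'
#' Resection specimens get the full four-protein panel. Biopsies start with
#' the two obligate heterodimer partners MSH6 and PMS2: presence of PMS2
#' certifies MLH1 and presence of MSH6 certifies MSH2, so the remaining
#' stains are only reflexed when their partner is lost (MLH1 after PMS2 loss,
#' MSH2 after MSH6 loss).
#'
#' @param specimen `"resection"` or `"biopsy"`
#' @param prior_results an [ihc_result()] from the initial biopsy panel, or
#'   `NULL` for the initial round
#' @return character vector of proteins to stain next (empty when the biopsy
#'   work-up is complete)
#' @export
select_panel <- function(specimen, prior_results = NULL) {
  specimen <- .match_one(specimen, c("resection", "biopsy"), "specimen")
  if (specimen == "resection") return(.mmr_genes)
  if (is.null(prior_results)) return(c("MSH6", "PMS2"))
  stopifnot(inherits(prior_results, "ihc_result"))
  s <- prior_results$stains
  reflex <- character(0)
  if (s[["PMS2"]] == "absent" && s[["MLH1"]] == "not_done") reflex <- c(reflex, "MLH1")
  if (s[["MSH6"]] == "absent" && s[["MSH2"]] == "not_done") reflex <- c(reflex, "MSH2")
  reflex
}

#' Derive the MMR loss pattern from an IHC result
#'
#' Patterns follow heterodimer biology: MLH1 loss destabilises PMS2 and MSH2
#' loss destabilises MSH6, so losses are reported as the familiar pairs plus
#' the isolated secondary-partner patterns. Weak-but-present stains count as
#' present (the weak flag is carried separately); a case with no absent stain
#' is `normal` when the informative stains were scored (directly or via a
#' present heterodimer partner) and `incomplete` otherwise.
#'
#' @param ihc an [ihc_result()]
#' @return a character scalar pattern, one of `MLH1_PMS2`, `MSH2_MSH6`,
#'   `MSH6_only`, `PMS2_only`, `normal`, `incomplete`, with attribute
#'   `weak` listing weak-present proteins
#' @export
loss_pattern <- function(ihc) {
  stopifnot(inherits(ihc, "ihc_result"))
  s <- ihc$stains
  absent <- names(s)[s == "absent"]
  weak <- names(s)[s == "weak_present"]
  pattern <-
    if ("MLH1" %in% absent) "MLH1_PMS2"
    else if ("MSH2" %in% absent) "MSH2_MSH6"
    else if (all(c("MSH6", "PMS2") %in% absent)) "PMS2_only"
    else if ("MSH6" %in% absent) "MSH6_only"
    else if ("PMS2" %in% absent) "PMS2_only"
    else {
      # no loss: MSH6 + PMS2 presence certifies the whole panel
      informative <- s[c("MSH6", "PMS2")] %in% c("present", "weak_present")
      if (all(informative)) "normal" else "incomplete"
    }
  structure(pattern, weak = weak)
}

#' Quantitative MLH1 promoter-methylation call
#'
#' The pyrosequencing assay reports per-CpG methylation percentages over the
#' promoter sites in one reaction; the test-level value is their arithmetic
#' mean and the call is positive when the mean reaches the threshold
#' (inclusive, default >= 15%). An empty measurement set is a failed test.
#'
#' @param cpg_levels numeric vector of per-site methylation percentages in
#'   \[0, 100\]; empty for a failed assay
#' @param threshold positivity threshold in percent (default 15)
#' @return a `methylation_result` list: `cpg_levels`, `mean_level`, `call`
#'   (`positive`, `negative` or `failed`)
#' @export
call_methylation <- function(cpg_levels, threshold = 15) {
  if (length(cpg_levels) == 0L) {
    return(structure(list(cpg_levels = numeric(0), mean_level = NA_real_,
                          call = "failed"), class = "methylation_result"))
  }
  .check_fraction(cpg_levels, "cpg_levels", lo = 0, hi = 100)
  m <- mean(cpg_levels)
  structure(list(cpg_levels = as.numeric(cpg_levels), mean_level = m,
                 call = if (m >= threshold) "positive" else "negative"),
            class = "methylation_result")
}

#' BRAF-V600E reflex rule for inferring MLH1 hypermethylation
#'
#' When direct MLH1 promoter-methylation testing fails on a biopsy (the only
#' tissue with too little DNA for the assay), positive BRAF-V600E IHC is
#' accepted as evidence of sporadic hypermethylation. The same inference is
#' drawn when the methylation test ran but returned a value within
#' `margin` percentage points below the positivity threshold and BRAF is
#' positive — a near-threshold negative on a BRAF-mutant tumour.
#'
#' @param specimen `"resection"` or `"biopsy"`
#' @param methylation a `methylation_result` from [call_methylation()], or
#'   `NULL` if no test was attempted
#' @param braf_ihc `"positive"`, `"negative"` or `"not_done"`
#' @param threshold methylation positivity threshold (percent)
#' @param margin rescue margin below the threshold (percentage points)
#' @return `"infer_mlh1_hm"` or `"no_inference"`
#' @export
braf_fallback <- function(specimen, methylation, braf_ihc,
                          threshold = 15, margin = 2) {
  specimen <- .match_one(specimen, c("resection", "biopsy"), "specimen")
  braf_ihc <- .match_one(braf_ihc, c("positive", "negative", "not_done"),
                         "braf_ihc")
  if (braf_ihc != "positive") return("no_inference")
  failed <- is.null(methylation) || methylation$call == "failed"
  if (failed) {
    return(if (specimen == "biopsy") "infer_mlh1_hm" else "no_inference")
  }
  if (methylation$call == "negative" &&
      methylation$mean_level >= threshold - margin) {
    return("infer_mlh1_hm")
  }
  "no_inference"
}
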