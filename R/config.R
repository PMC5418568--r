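#' Default run configuration
#'
#' Nested list of every tunable threshold in the pipeline, in the shape the
#' JSON configuration files use. Values are the study defaults; see the
#' methods vignette for the rationale behind each.
#'
#' * `screening$methylation_threshold` — mean CpG methylation (percent) at or
#'   above which a tumour is called MLH1-hypermethylated (default 15).
#' * `screening$braf_rescue_margin` — percentage points below the methylation
#'   threshold within which a negative test may still be rescued by positive
#'   BRAF-V600E IHC (default 2).
#' * `somatic$msi_threshold` — mSINGS unstable-locus fraction at or above
#'   which a tumour is MSI-high (default 0.2, inclusive).
#' * `somatic$loh_bands` — observed/expected VAF ratio cut-offs for the
#'   definite/likely/maybe LOH bands.
#' * `association$correction_factors` — per-trait genomic-inflation factors
#'   (LD-score regression intercepts supplied as configuration constants).
#' * `sv` — discordant-pair scanner knobs: flank (bp), minimum discordant-pair
#'   support, cluster gap (bp), control-catalogue fraction above which a
#'   cluster is treated as a common variant, and insert-size trimming.
#'
#' @return nested list of settings
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    screening = list(
      methylation_threshold = 15,
      braf_rescue_margin = 2
    ),
    somatic = list(
      msi_threshold = 0.2,
      loh_bands = c(definite = 0.95, likely = 0.85, maybe = 0.60)
    ),
    association = list(
      alpha = 0.05,
      n_tests = 16L,
      correction_factors = correction_factors()
    ),
    sv = list(
      flank = 100000L,
      min_support = 3L,
      max_gap = 500L,
      max_control_fraction = 0.01,
      insert_trim = 0.01,
      max_insert_pairs = 100000L
    )
  )
}

#' Read / write a JSON run configuration
#'
#' @param path file path
#' @return `read_config()` returns the nested settings list, with any field
#'   missing from the file filled from [default_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), raw)
  cfg
}

#' @rdname read_config
#' @param config nested settings list
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Genomic-inflation correction factors by trait
#'
#' LD-score regression intercepts used to deflate association chi-square
#' statistics, keyed by cancer type. These are configuration constants for
#' [correct_inflation()]; the package does not estimate them.
#'
#' @return named numeric vector of 17 per-trait factors
#' @export
correction_factors <- function() {
  c(colorectal      = 1.15,
    colon           = 1.12,
    rectal          = 1.04,
    endometrial     = 1.05,
    ovarian         = 1.04,
    brain           = 1.03,
    breast          = 1.25,
    bladder         = 1.07,
    esophageal      = 1.02,
    gallbladder     = 1.01,
    gastric         = 1.13,
    liver           = 1.02,
    myelodysplastic = 1.00,
    pancreatic      = 1.09,
    prostate        = 1.22,
    renal           = 1.01,
    testicular      = 1.03)
}
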