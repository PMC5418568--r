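# Case-control logistic association, inflation correction, multiplicity,
# carrier-prevalence aggregation and odds-ratio -> lifetime-risk conversion.

.assoc_result <- function(or_hat, ci, p, chi2, n_cases, n_controls,
                          flagged = FALSE, variant_id = NA_character_,
                          cancer = NA_character_, info = NA_real_) {
  tibble::tibble(variant_id = variant_id, cancer = cancer,
                 or_hat = or_hat, ci_low = ci[1], ci_high = ci[2],
                 p_raw = p, chi2_raw = chi2,
                 correction_factor = 1, p_corrected = p,
                 n_cases = n_cases, n_controls = n_controls,
                 info = info, flagged = flagged)
}

#' Fit a case-control logistic association
#'
#' Maximum-likelihood logistic regression of case status on genotype
#' dosage; the slope is exponentiated to an odds ratio with a Wald 95%
#' confidence interval and a Wald chi-square p-value. With 0/1 dosages the
#' fit is performed on the aggregated 2x2 counts (the identical binomial
#' likelihood), where the ML odds ratio equals the cross-product ratio.
#' Complete separation — a zero cell in the 2x2 — yields a flagged estimate
#' with an infinite (or zero) bound rather than an error.
#'
#' @param genotype_dosage numeric dosage per individual (0/1 for carrier
#'   status; fractional dosages are fitted as given)
#' @param status logical or 0/1 case indicator
#' @param variant_id,cancer,info optional metadata carried through
#' @return one-row tibble: `or_hat`, `ci_low`, `ci_high`, `p_raw`,
#'   `chi2_raw`, `correction_factor`, `p_corrected`, counts, `flagged`
#' @export
fit_association <- function(genotype_dosage, status,
                            variant_id = NA_character_,
                            cancer = NA_character_, info = NA_real_) {
  status <- as.integer(status)
  if (length(genotype_dosage) != length(status)) {
    stop("dosage and status lengths differ", call. = FALSE)
  }
  if (!any(status == 1L) || !any(status == 0L)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (length(unique(genotype_dosage)) < 2L) {
    stop("genotype dosage is constant", call. = FALSE)
  }
  n_cases <- sum(status == 1L)
  n_controls <- sum(status == 0L)
  if (all(genotype_dosage %in% c(0, 1))) {
    counts <- list(
      case_carrier = sum(status == 1L & genotype_dosage == 1),
      case_noncarrier = sum(status == 1L & genotype_dosage == 0),
      control_carrier = sum(status == 0L & genotype_dosage == 1),
      control_noncarrier = sum(status == 0L & genotype_dosage == 0))
    return(fit_association_counts(counts, variant_id = variant_id,
                                  cancer = cancer, info = info))
  }
  fit <- stats::glm(status ~ genotype_dosage, family = stats::binomial())
  beta <- stats::coef(fit)[["genotype_dosage"]]
  se <- sqrt(stats::vcov(fit)["genotype_dosage", "genotype_dosage"])
  chi2 <- (beta / se)^2
  .assoc_result(exp(beta), exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                stats::pchisq(chi2, df = 1, lower.tail = FALSE), chi2,
                n_cases, n_controls, variant_id = variant_id,
                cancer = cancer, info = info)
}

#' @rdname fit_association
#' @param counts list or vector with `case_carrier`, `case_noncarrier`,
#'   `control_carrier`, `control_noncarrier` (as from
#'   [simulate_case_control()])
#' @export
fit_association_counts <- function(counts, variant_id = NA_character_,
                                   cancer = NA_character_, info = NA_real_) {
  a <- counts[["case_carrier"]]
  b <- counts[["case_noncarrier"]]
  c_ <- counts[["control_carrier"]]
  d <- counts[["control_noncarrier"]]
  n_cases <- a + b
  n_controls <- c_ + d
  if (min(a, b, c_, d) == 0) {
    num <- a * d
    den <- b * c_
    or <- if (num == 0 && den == 0) NA_real_ else if (den == 0) Inf else
      num / den
    return(.assoc_result(or, c(0, Inf), NA_real_, NA_real_, n_cases,
                         n_controls, flagged = TRUE, variant_id = variant_id,
                         cancer = cancer, info = info))
  }
  # grouped binomial logistic fit: same ML problem as the per-individual fit
  carrier <- c(0, 1)
  fit <- stats::glm(cbind(c(b, a), c(d, c_)) ~ carrier,
                    family = stats::binomial())
  beta <- stats::coef(fit)[["carrier"]]
  se <- sqrt(stats::vcov(fit)["carrier", "carrier"])
  chi2 <- (beta / se)^2
  .assoc_result(exp(beta), exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                stats::pchisq(chi2, df = 1, lower.tail = FALSE), chi2,
                n_cases, n_controls, variant_id = variant_id,
                cancer = cancer, info = info)
}

#' Deflate an association chi-square by a genomic-inflation factor
#'
#' Cryptic relatedness and stratification inflate association test
#' statistics; the LD-score regression intercept for the trait is applied
#' as a divisor and the p-value recomputed from the 1-df chi-square.
#'
#' @param chi2_raw uncorrected chi-square statistic
#' @param factor inflation factor (> 0); see [correction_factors()]
#' @return list with `chi2_corrected` and `p_corrected`
#' @export
correct_inflation <- function(chi2_raw, factor) {
  if (!is.numeric(factor) || any(factor <= 0)) {
    stop("inflation factor must be > 0", call. = FALSE)
  }
  chi2 <- chi2_raw / factor
  list(chi2_corrected = chi2,
       p_corrected = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate
#' @param m number of tests
#' @return `alpha / m`, with a `label` attribute formatted to 3 significant
#'   figures as conventionally printed
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 16L) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  thr <- alpha / m
  structure(thr, label = formatC(signif(thr, 3), format = "g", digits = 3))
}

#' Combined carrier prevalence of several mutations
#'
#' Union under carrier independence, `1 - prod(1 - f_i)`; for rare variants
#' this is the sum of the frequencies to within a few parts per million.
#'
#' @param freqs numeric carrier fractions
#' @return combined prevalence fraction
#' @export
carrier_prevalence <- function(freqs) {
  if (!length(freqs)) return(0)
  .check_fraction(freqs, "freqs")
  1 - prod(1 - freqs)
}

#' Convert an odds ratio to a carrier lifetime risk
#'
#' Given the general-population cumulative cancer risk to age 75 (`baseline`)
#' and a carrier odds ratio, the carrier risk is computed either on the
#' odds scale (carrier odds = OR x baseline odds, the scale on which
#' logistic odds ratios live) or on the hazard scale
#' (`1 - (1 - baseline)^OR`). Both are strictly increasing in both
#' arguments and return the baseline unchanged at OR = 1.
#'
#' @param or_val odds ratio (> 0)
#' @param baseline baseline cumulative risk in (0, 1)
#' @param formula `"odds_scale"` (default) or `"hazard_scale"`
#' @return carrier cumulative risk fraction
#' @export
risk_from_or <- function(or_val, baseline, formula = c("odds_scale",
                                                       "hazard_scale")) {
  formula <- match.arg(formula)
  stopifnot(all(or_val > 0))
  .check_fraction(baseline, "baseline", open = TRUE)
  if (formula == "odds_scale") {
    or_val * baseline / (1 - baseline + or_val * baseline)
  } else {
    1 - (1 - baseline)^or_val
  }
}

#' @rdname risk_from_or
#' @param carrier_risk carrier cumulative risk in (0, 1)
#' @return `baseline_from_risk()` inverts the conversion, recovering the
#'   baseline risk from a carrier risk and the odds ratio.
#' @export
baseline_from_risk <- function(carrier_risk, or_val,
                               formula = c("odds_scale", "hazard_scale")) {
  formula <- match.arg(formula)
  stopifnot(all(or_val > 0))
  .check_fraction(carrier_risk, "carrier_risk", open = TRUE)
  if (formula == "odds_scale") {
    odds <- carrier_risk / (1 - carrier_risk) / or_val
    odds / (1 + odds)
  } else {
    1 - (1 - carrier_risk)^(1 / or_val)
  }
}

#' Concordance between imputed and directly measured genotypes
#'
#' @param imputed,direct equal-length genotype call vectors; `NA` in
#'   `direct` marks an unmeasured pair, excluded from the denominator
#' @return fraction of matching calls
#' @export
imputation_concordance <- function(imputed, direct) {
  if (length(imputed) != length(direct)) {
    stop("call vectors differ in length", call. = FALSE)
  }
  keep <- !is.na(direct)
  if (!any(keep)) {
    stop("undefined metric: no directly measured genotypes to compare",
         call. = FALSE)
  }
  mean(imputed[keep] == direct[keep])
}
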