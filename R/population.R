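# Population-scale genotype/phenotype simulation for rare founder variants.

#' Population simulation configuration
#'
#' @param n_individuals population size
#' @param carrier_freq named carrier fraction per mutation
#' @param cancer_baseline_risk named baseline cumulative incidence (to age
#'   75) per cancer type, in (0, 1)
#' @param true_or odds-ratio matrix, mutations in rows, cancers in columns
#'   (or a single number recycled); all entries > 0
#' @param seed integer RNG seed
#' @return a validated `population_config` list
#' @export
population_config <- function(n_individuals, carrier_freq,
                              cancer_baseline_risk, true_or, seed = 1L) {
  .check_fraction(carrier_freq, "carrier_freq")
  .check_fraction(cancer_baseline_risk, "cancer_baseline_risk", open = TRUE)
  m <- length(carrier_freq)
  k <- length(cancer_baseline_risk)
  or_mat <- matrix(true_or, nrow = m, ncol = k,
                   dimnames = list(names(carrier_freq),
                                   names(cancer_baseline_risk)))
  if (any(or_mat <= 0)) stop("true_or must be > 0", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 carrier_freq = carrier_freq,
                 cancer_baseline_risk = cancer_baseline_risk,
                 true_or = or_mat, seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a population genotype/phenotype table
#'
#' Each individual's carrier status per mutation is an independent Bernoulli
#' draw at the configured carrier frequency; each per-cancer affection
#' status comes from a logistic model in which every carried mutation
#' multiplies the baseline odds by its configured odds ratio.
#'
#' @param config a [population_config()]
#' @return tibble with one row per individual: `id`, `sex`, one
#'   `carrier_<mutation>` column per mutation and one `case_<cancer>` column
#'   per cancer type
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  out <- tibble::tibble(id = sprintf("P%07d", seq_len(n)),
                        sex = sample(c("male", "female"), n, replace = TRUE))
  muts <- names(config$carrier_freq)
  G <- matrix(0L, nrow = n, ncol = length(muts))
  for (j in seq_along(muts)) {
    G[, j] <- stats::rbinom(n, 1L, config$carrier_freq[j])
    out[[paste0("carrier_", muts[j])]] <- G[, j]
  }
  for (cc in names(config$cancer_baseline_risk)) {
    eta <- stats::qlogis(config$cancer_baseline_risk[[cc]]) +
      as.vector(G %*% log(config$true_or[, cc]))
    out[[paste0("case_", cc)]] <- stats::rbinom(n, 1L, stats::plogis(eta))
  }
  out
}

#' Simulate carrier counts for a fixed case-control design
#'
#' Retrospective sampling that honours fixed case and control totals:
#' controls carry the variant at the population carrier frequency, and
#' carrier odds among cases equal the control carrier odds multiplied by
#' the true odds ratio (the case-control duality of the logistic model).
#'
#' @param n_cases,n_controls design totals
#' @param carrier_freq control carrier fraction
#' @param true_or true carrier odds ratio
#' @return list of the four 2x2 counts: `case_carrier`, `case_noncarrier`,
#'   `control_carrier`, `control_noncarrier`
#' @export
simulate_case_control <- function(n_cases, n_controls, carrier_freq,
                                  true_or) {
  .check_fraction(carrier_freq, "carrier_freq")
  stopifnot(true_or > 0)
  control_odds <- carrier_freq / (1 - carrier_freq)
  case_odds <- true_or * control_odds
  p_case <- case_odds / (1 + case_odds)
  a <- stats::rbinom(1, n_cases, p_case)
  c_ <- stats::rbinom(1, n_controls, carrier_freq)
  list(case_carrier = a, case_noncarrier = n_cases - a,
       control_carrier = c_, control_noncarrier = n_controls - c_)
}
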