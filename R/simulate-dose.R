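#' Configuration for a simulated dose-lethality experiment
#'
#' Death probability follows a Hill curve on linear dose,
#' \eqn{P(\mathrm{death}\mid d) = d^h / (d^h + \mathrm{LD50}^h)}, with the
#' log-LD50 shifted by \code{age_sensitivity} per day of adult age relative
#' to the reference assay age, so older cohorts are more sensitive when the
#' shift is negative.  The default LD50 of 10 mM matches roughly half
#' lethality after 24 h exposure to a 10 mM glutathione-depleting challenge
#' in day-4 adults.
#'
#' @param doses vector of doses, mM (>= 0).
#' @param n_per_dose animals per dose (>= 1).
#' @param ld50 LD50 at the reference age, mM.
#' @param hill_slope Hill coefficient h.
#' @param age_sensitivity shift of log-LD50 per day of age.
#' @param age cohort adult age, days.
#' @param reference_age age at which \code{ld50} applies, days.
#' @param seed integer RNG seed.
#' @return A list of class \code{"dose_sim_config"}.
#' @export
dose_sim_config <- function(doses = c(0, 1, 2.5, 5, 10, 15, 20),
                            n_per_dose = 30, ld50 = 10, hill_slope = 3,
                            age_sensitivity = -0.1, age = 4,
                            reference_age = 4, seed = 1) {
  check_nonneg(doses, "doses")
  if (n_per_dose < 1) stopf("'n_per_dose' must be >= 1")
  check_positive(ld50, "ld50")
  check_positive(hill_slope, "hill_slope")
  structure(list(doses = doses, n_per_dose = as.integer(n_per_dose),
                 ld50 = ld50, hill_slope = hill_slope,
                 age_sensitivity = age_sensitivity, age = age,
                 reference_age = reference_age, seed = seed),
            class = "dose_sim_config")
}

hill_p <- function(dose, ld50, h) {
  ifelse(dose <= 0, 0, dose^h / (dose^h + ld50^h))
}

#' Generate per-animal dose-lethality outcomes
#'
#' @param config a [dose_sim_config()].
#' @return A data frame with one row per animal: \code{dose}, \code{age},
#'   \code{dead} (0/1); truth (effective LD50 at this age, Hill slope)
#'   attached as \code{"truth"}.
#' @export
gen_dose_response <- function(config) {
  if (!inherits(config, "dose_sim_config"))
    stopf("'config' must be a dose_sim_config")
  set_seed_if(config$seed)
  ld50_age <- exp(log(config$ld50) +
                  config$age_sensitivity * (config$age - config$reference_age))
  rows <- lapply(config$doses, function(d) {
    p <- hill_p(d, ld50_age, config$hill_slope)
    data.frame(dose = d, age = config$age,
               dead = rbinom(config$n_per_dose, 1, p))
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(config = config, ld50_at_age = ld50_age,
                             hill_slope = config$hill_slope)
  out
}
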