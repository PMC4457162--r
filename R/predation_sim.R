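# Synthetic field-predation generator: artificial prey models pinned out
# along transects, checked every 4 h over 48 h.

#' Simulate field predation on artificial prey models
#'
#' Attack times are exponential with
#' `log hazard = log(baseline_hazard) - hazard_coefficient * JND`, so more
#' conspicuous models (higher chromatic contrast against their local
#' background) are attacked at a lower rate. Observed times are rounded
#' UP to the next check (an attack is detected at the first check after it
#' happens); models unattacked at the administrative limit are
#' right-censored, and an independent `censor_fraction` of models is
#' removed early for non-predator reasons (rodent bites, degradation,
#' slug slime), mirroring the field censoring rules.
#'
#' @param models Data frame with columns `colour` (label) and `jnd`
#'   (chromatic JND against the local background); optional `transect`.
#' @param hazard_coefficient Log-hazard change per JND (>= 0 means
#'   conspicuous models are attacked less; default 0.065).
#' @param baseline_hazard Attack hazard per hour at JND 0 (default 0.003).
#' @param check_interval Hours between checks (default 4); must divide
#'   `admin_censor_time`.
#' @param admin_censor_time Total exposure in hours (default 48).
#' @param censor_fraction Fraction of models lost early to non-predator
#'   causes (default 0.05).
#' @param seed Optional integer seed.
#' @return Data frame `model_id, colour, transect, time_h, status
#'   (attacked/censored), reason (none/rodent/degraded/slime/
#'   administrative), jnd`, with attribute `true_attack_time` (the latent
#'   continuous times).
#' @export
simulate_field_predation <- function(models, hazard_coefficient = 0.065,
                                     baseline_hazard = 0.003,
                                     check_interval = 4,
                                     admin_censor_time = 48,
                                     censor_fraction = 0.05, seed = NULL) {
  stopifnot(all(c("colour", "jnd") %in% names(models)))
  if (baseline_hazard < 0 || hazard_coefficient < 0) {
    stop("hazard inputs must be non-negative")
  }
  if (abs(admin_censor_time / check_interval -
          round(admin_censor_time / check_interval)) > 1e-9) {
    stop("check_interval must divide admin_censor_time")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(models)
  lambda <- baseline_hazard * exp(-hazard_coefficient * models$jnd)
  t_attack <- ifelse(lambda > 0, rexp(n, pmax(lambda, 1e-300)), Inf)
  if (baseline_hazard == 0) t_attack <- rep(Inf, n)
  grid <- seq(check_interval, admin_censor_time, by = check_interval)
  # round up to the first check after the attack
  t_obs <- check_interval * ceiling(t_attack / check_interval)
  status <- ifelse(t_attack <= admin_censor_time, "attacked", "censored")
  reason <- ifelse(status == "censored", "administrative", "none")
  time_h <- pmin(t_obs, admin_censor_time)
  # early non-predator losses: a random subset censored at a random check
  lost <- runif(n) < censor_fraction
  t_lost <- sample(grid, n, replace = TRUE)
  overt <- lost & (t_lost < t_attack)
  if (any(overt)) {
    time_h[overt] <- t_lost[overt]
    status[overt] <- "censored"
    reason[overt] <- sample(c("rodent", "degraded", "slime"),
                            sum(overt), replace = TRUE)
  }
  out <- data.frame(
    model_id = sprintf("m%04d", seq_len(n)),
    colour = models$colour,
    transect = if ("transect" %in% names(models)) models$transect else 1L,
    time_h = time_h, status = status, reason = reason, jnd = models$jnd
  )
  attr(out, "true_attack_time") <- t_attack
  out
}
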