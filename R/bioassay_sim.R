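# Synthetic Daphnia bioassay generator.
#
# One ladybird extract is assayed at seven dilutions (100, 80, 60, 50, 40,
# 20 and 0% of stock), ten Daphnia per vial, deaths counted at 1, 3 and
# 24 h. The generator draws a death time per Daphnia from a constant
# hazard combining background mortality with a toxin hazard that is
# logistic in log-dose, so dead counts are Binomial at every time point
# and non-decreasing in both dose and time within a vial.

.default_dilutions <- c(1.0, 0.8, 0.6, 0.5, 0.4, 0.2, 0.0)

# 3 h kill probability per dilution for a given log-LC50.
.bioassay_p3 <- function(dilutions, log_lc50, slope, background_rate) {
  p0 <- 1 - exp(-background_rate * 3)
  ptox <- ifelse(dilutions > 0,
                 plogis(slope * (log(dilutions) - log_lc50)), 0)
  1 - (1 - p0) * (1 - ptox)
}

#' Simulate a Daphnia dose-response bioassay
#'
#' `true_toxicity` is the expected mean number of dead Daphnia (out of
#' `n_daphnia`) per vial at 3 h, averaged across the dilution series --
#' the same scale as the downstream toxicity response. The generator
#' solves for the latent LC50 that produces this mean under a logistic
#' dose-response of the stated slope, then draws exponential death times.
#'
#' @param true_toxicity Target mean dead at 3 h (>= 0); 0 means no toxin.
#' @param dilutions Dilution fractions in `[0, 1]` (default the 7-point
#'   series 100/80/60/50/40/20/0%).
#' @param n_daphnia Daphnia per vial (default 10).
#' @param slope Logistic dose-response steepness on log-dose (default 3).
#' @param times Observation times in hours (default 1, 3, 24).
#' @param background_rate Background mortality hazard per hour in clean
#'   water (default 0.02; not reported for the original assay, exposed as
#'   a parameter).
#' @param seed Optional integer seed.
#' @param specimen_id Identifier written into the records.
#' @return Data frame `specimen_id, dilution, time_h, dead, n` with
#'   attribute `true_lc50` (dilution fraction, `Inf` when no toxin
#'   hazard was needed).
#' @export
simulate_bioassay <- function(true_toxicity, dilutions = .default_dilutions,
                              n_daphnia = 10, slope = 3,
                              times = c(1, 3, 24), background_rate = 0.02,
                              seed = NULL, specimen_id = "specimen") {
  if (any(dilutions < 0 | dilutions > 1)) stop("dilutions must lie in [0, 1]")
  if (true_toxicity < 0) stop("true_toxicity must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p0 <- 1 - exp(-background_rate * 3)
  nd <- length(dilutions)
  m_min <- n_daphnia * p0
  m_max <- n_daphnia * mean(ifelse(dilutions > 0, 1, p0))
  m <- min(max(true_toxicity, m_min), m_max * 0.999)
  if (true_toxicity <= m_min + 1e-12) {
    log_lc50 <- Inf  # no toxin hazard needed
  } else {
    f <- function(ll) {
      n_daphnia * mean(.bioassay_p3(dilutions, ll, slope, background_rate)) - m
    }
    log_lc50 <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  p3 <- .bioassay_p3(dilutions, log_lc50, slope, background_rate)
  # per-vial total hazard reproducing p3 at 3 h
  lambda <- -log(1 - p3) / 3
  nt <- length(times)
  dead <- integer(nd * nt)
  for (j in seq_len(nd)) {
    tdeath <- if (lambda[j] > 0) rexp(n_daphnia, lambda[j]) else Inf
    dead[(j - 1L) * nt + seq_len(nt)] <-
      vapply(times, function(t) sum(tdeath <= t), 0L)
  }
  out <- data.frame(specimen_id = specimen_id,
                    dilution = rep(dilutions, each = nt),
                    time_h = rep(times, nd), dead = dead, n = n_daphnia)
  attr(out, "true_lc50") <- exp(log_lc50)
  out
}
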