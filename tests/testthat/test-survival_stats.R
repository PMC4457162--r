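# Kaplan-Meier, Cox (vs the survival package as oracle), contrasts.

test_that("product-limit estimator matches hand computation", {
  expect_true(all(km_surv(kaplan_meier(c(5, 10, 20), c(FALSE, FALSE, FALSE)),
                          c(1, 10, 50)) == 1))

  km <- kaplan_meier(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(km$table$surv, c(3 / 4, 1 / 2, 1 / 4))
  expect_equal(km$table$n_risk, c(4, 3, 2))

  # duplicating every record leaves S(t) unchanged
  t0 <- c(2, 4, 4, 8, 12); e0 <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  k1 <- kaplan_meier(t0, e0)
  k2 <- kaplan_meier(rep(t0, 2), rep(e0, 2))
  expect_equal(k1$table$surv, k2$table$surv)

  expect_error(kaplan_meier(c(0, 1), c(TRUE, TRUE)), "positive")
  expect_error(kaplan_meier(numeric(0), logical(0)), "one record")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(15)
  for (i in 1:10) {
    t <- sample(1:8, 20, replace = TRUE)
    km <- kaplan_meier(t, rep(TRUE, 20))
    # oracle: empirical P(T > t)
    expect_equal(km$table$surv,
                 vapply(km$table$time, function(ti) mean(t > ti), 0))
  }
  # Greenwood standard errors present and finite where S > 0
  km <- kaplan_meier(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(is.finite(km$table$std_err[km$table$surv > 0])))
})

test_that("Cox fit reproduces the survival package (Breslow, strata)", {
  skip_if_not_installed("survival")
  set.seed(16)
  n <- 250
  d <- data.frame(time = ceiling(rexp(n, 0.05)), event = runif(n) < 0.6,
                  colour = factor(sample(c("a", "b", "c"), n, TRUE)),
                  jnd = rnorm(n, 5, 2),
                  transect = sample(1:3, n, TRUE))
  mine <- fit_cox(d, ~ colour + jnd, strata = "transect")
  ref <- survival::coxph(survival::Surv(time, event) ~ colour + jnd +
                           survival::strata(transect),
                         data = d, ties = "breslow")
  expect_equal(mine$coef, coef(ref), tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(unname(mine$loglik[2]), ref$loglik[2], tolerance = 1e-8)

  # unstratified too
  mine2 <- fit_cox(d, ~ jnd)
  ref2 <- survival::coxph(survival::Surv(time, event) ~ jnd, data = d,
                          ties = "breslow")
  expect_equal(unname(mine2$coef), unname(coef(ref2)), tolerance = 1e-7)
})

test_that("Cox null, invariance and diagnostics", {
  set.seed(17)
  d <- data.frame(time = rexp(200, 0.1), event = TRUE,
                  colour = factor(rep(c("a", "b"), 100)))
  f <- fit_cox(d, ~ colour)
  expect_lt(abs(f$z[1]), 3)

  # rescaling time leaves hazard ratios unchanged
  d2 <- transform(d, time = time * 7.3)
  f2 <- fit_cox(d2, ~ colour)
  expect_equal(f$coef, f2$coef, tolerance = 1e-9)

  # no events in a level -> identifiability error
  d3 <- d; d3$event[d3$colour == "b"] <- FALSE
  expect_error(fit_cox(d3, ~ colour), "not identifiable")

  # monotone likelihood: covariate perfectly ordering the event times
  d4 <- data.frame(time = 1:40, event = TRUE, x = 40:1)
  expect_error(fit_cox(d4, ~ x), "separation|singular")
})

test_that("hazard-ratio recovery at field scale", {
  set.seed(18)
  hr <- replicate(25, {
    n <- 750
    colour <- rep(c("dull", "bright"), each = n / 2)
    lambda <- ifelse(colour == "dull", 0.002, 0.001)  # HR 2
    t <- rexp(n, lambda)
    d <- data.frame(time = pmin(4 * ceiling(t / 4), 48),
                    event = t <= 48,
                    colour = factor(colour, levels = c("bright", "dull")))
    exp(fit_cox(d, ~ colour)$coef[["colourdull"]])
  })
  expect_gt(median(hr), 1.7)
  expect_lt(median(hr), 2.3)
})

test_that("pairwise contrasts: antisymmetry, self-pair, unknown levels", {
  set.seed(19)
  d <- data.frame(time = rexp(300, 0.1), event = runif(300) < 0.8,
                  colour = factor(sample(c("red", "brown", "black"), 300, TRUE)))
  f <- fit_cox(d, ~ colour)
  pw <- pairwise_survival(f)
  expect_equal(nrow(pw), 3)
  ab <- pairwise_survival(f, pairs = cbind("red", "brown"))
  ba <- pairwise_survival(f, pairs = cbind("brown", "red"))
  expect_equal(ab$coef, -ba$coef)
  expect_equal(ab$p, ba$p)
  self <- pairwise_survival(f, pairs = cbind("red", "red"))
  expect_equal(self$coef, 0)
  expect_error(pairwise_survival(f, pairs = cbind("red", "violet")),
               "unknown level")
  # multiplicity flag
  pw_adj <- pairwise_survival(f, p_adjust = "bonferroni")
  expect_true(all(pw_adj$p >= pw$p - 1e-12))
})

test_that("attack rate with exact binomial interval", {
  rec <- data.frame(time_h = 4, status = c(rep("attacked", 50),
                                           rep("censored", 700)))
  ar <- attack_rate(rec)
  expect_equal(ar$rate, 50 / 750, tolerance = 1e-9)
  expect_equal(ar$n_attacked, 50)
  expect_true(ar$ci[1] < ar$rate && ar$rate < ar$ci[2])

  set.seed(20)
  expect_equal(attack_rate(rec[sample(nrow(rec)), ])$rate, ar$rate)

  none <- data.frame(time_h = 48, status = rep("censored", 20))
  ar0 <- attack_rate(none)
  expect_equal(ar0$rate, 0)
  expect_equal(ar0$ci[1], 0)
  expect_error(attack_rate(rec[0, ]), "no records")
})
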