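# Honesty regressions, within-species tests, robustness, field association.

# cheap synthetic specimen table with a controllable contrast-toxicity link
toy_table <- function(n_per = 20, slope = 0.1, within_sat_r = 0,
                      species = c("red", "yellow", "brown", "black")) {
  rows <- lapply(seq_along(species), function(si) {
    jnd <- 5 * si + rnorm(n_per, 0, 1.5)
    eps <- rnorm(n_per, 0, 0.2)
    sat <- 0.1 * si + within_sat_r * eps + rnorm(n_per, 0, 0.02)
    data.frame(
      specimen_id = sprintf("%s_%d", species[si], seq_len(n_per)),
      species = species[si], size_mm = rnorm(n_per, 4.5, 0.3),
      weight_g = rnorm(n_per, 0.012, 0.001),
      luminance = runif(n_per, 0.1, 0.5), saturation = sat,
      area_cm2 = runif(n_per, 0.1, 0.2),
      background_chromatic_jnd = jnd,
      background_achromatic_jnd = jnd / 2 + rnorm(n_per, 0, 1),
      internal_dl = runif(n_per, 1, 20),
      log_toxicity = 0.2 + slope * jnd + eps)
  })
  do.call(rbind, rows)
}

test_that("honesty model recovers the contrast slope and survives permutation", {
  set.seed(21)
  tab <- toy_table(slope = 0.1)
  fit <- fit_honesty_model(tab)
  expect_gt(fit$contrast_effect$estimate, 0)
  expect_lt(fit$contrast_effect$p_value, 0.01)
  expect_equal(fit$contrast_effect$estimate, 0.1, tolerance = 0.3)
  expect_true("species" %in% fit$retained_terms)

  # permuting the response severs the association
  set.seed(22)
  perm_est <- replicate(20, {
    tabp <- tab
    tabp$log_toxicity <- sample(tabp$log_toxicity)
    fit_honesty_model(tabp, select = FALSE)$contrast_effect$estimate
  })
  expect_lt(abs(mean(perm_est)), 0.02)

  expect_error(fit_honesty_model(tab[tab$species == "red", ]), "2 species")
})

test_that("missing values and constant predictors are reported, not silent", {
  set.seed(23)
  tab <- toy_table()
  tab$luminance[3] <- NA
  tab$area_cm2 <- 0.15   # constant
  fit <- fit_honesty_model(tab)
  expect_equal(fit$na_report, tab$specimen_id[3])
  expect_equal(fit$dropped_constant, "area_cm2")
  expect_equal(fit$n, nrow(tab) - 1)
})

test_that("within-species saturation test: centring, power, null", {
  set.seed(24)
  tab <- toy_table(within_sat_r = 1)
  ws <- within_species_saturation_test(tab)
  centred <- unlist(lapply(split(tab$saturation, tab$species),
                           function(x) x - mean(x)))
  expect_equal(mean(abs(tapply(centred, rep(names(table(tab$species)),
                                            each = 20), mean))), 0,
               tolerance = 1e-12)
  expect_gt(ws$pooled_slope, 0)
  expect_lt(ws$p_value, 0.05)
  expect_equal(nrow(ws$per_species), 4)

  # within-species shuffle kills the slope on average
  set.seed(25)
  null_slopes <- replicate(20, {
    tabp <- tab
    tabp$saturation <- unlist(lapply(split(tab$saturation, tab$species),
                                     sample))
    within_species_saturation_test(tabp)$pooled_slope
  })
  expect_lt(abs(mean(null_slopes)), 0.05)

  # small species excluded with a warning
  tab_small <- rbind(tab, transform(tab[1:3, ], species = "tiny",
                                    specimen_id = paste0("t", 1:3)))
  expect_warning(ws2 <- within_species_saturation_test(tab_small), "tiny")
  expect_equal(ws2$n_species, 4)
})

test_that("leave-one-species-out flags single-species-driven associations", {
  set.seed(26)
  # association carried by one species only
  tab <- toy_table(slope = 0)
  carrier <- tab$species == "red"
  tab$log_toxicity[carrier] <- tab$log_toxicity[carrier] +
    0.4 * tab$background_chromatic_jnd[carrier]
  rep1 <- leave_one_species_out(tab)
  expect_false(rep1$contrast_stable)

  # association present in every species -> stable under all exclusions
  set.seed(27)
  tab2 <- toy_table(slope = 0.15)
  rep2 <- leave_one_species_out(tab2)
  expect_true(rep2$contrast_stable)

  expect_error(leave_one_species_out(toy_table(species = c("a", "b"))),
               "3 species")
})

test_that("survival-conspicuousness association: recovery, null, degenerate", {
  set.seed(28)
  models <- data.frame(colour = rep(c("a", "b", "c"), each = 120),
                       jnd = runif(360, 1, 25),
                       transect = rep(1:6, 60))
  rec <- simulate_field_predation(models, hazard_coefficient = 0.15,
                                  baseline_hazard = 0.02,
                                  censor_fraction = 0, seed = 29)
  rep <- survival_vs_conspicuousness(rec)
  expect_true(rep$defined)
  expect_lt(rep$logistic$estimate, 0)
  expect_lt(rep$cox$estimate, 0)
  expect_lt(rep$cox$p_value, 0.05)
  expect_match(rep$direction, "fewer attacks")

  # null world: association absent more often than not (single draw, just
  # check it runs and produces a two-sided p)
  rec0 <- simulate_field_predation(models, hazard_coefficient = 0,
                                   baseline_hazard = 0.02,
                                   censor_fraction = 0, seed = 30)
  rep0 <- survival_vs_conspicuousness(rec0)
  expect_true(rep0$defined)
  expect_true(rep0$logistic$p_value >= 0 && rep0$logistic$p_value <= 1)

  const <- rec; const$jnd <- 5
  expect_warning(repc <- survival_vs_conspicuousness(const), "constant JND")
  expect_false(repc$defined)
  expect_error(survival_vs_conspicuousness(transform(rec, jnd = NA)),
               "unmatched")
})
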