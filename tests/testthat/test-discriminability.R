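# Receptor-noise-limited discriminability.

test_that("receptor noise derives omegas from abundances", {
  n <- receptor_noise()
  expect_equal(unname(n$omega[["lw"]]), 0.05)  # most abundant cone = nu
  expect_equal(unname(n$omega[["uv"]]), 0.05 / sqrt(0.37), tolerance = 1e-12)
  expect_error(receptor_noise(abundances = c(uv = -1, sw = 1, mw = 1, lw = 1)),
               "positive")
  expect_error(receptor_noise(weber = 0), "positive")
})

test_that("chromatic JND closed-form anchors", {
  base <- cone_catch(0.3, 0.3, 0.3, 0.3, 0.3)
  expect_equal(chromatic_jnd(base, base, default_noise), 0)

  # equal omegas 0.05, delta-f = (0.05, 0, 0, 0): dS = sqrt(0.75)
  a <- displaced_catch(base, c(0.05, 0, 0, 0))
  expect_equal(chromatic_jnd(a, base, equal_noise), sqrt(0.75),
               tolerance = 1e-12)

  # dichromat closed form
  set.seed(7)
  for (i in 1:20) {
    x <- random_catch(); y <- random_catch()
    df <- log(unclass(x)[c("uv", "sw")] / unclass(y)[c("uv", "sw")])
    om <- default_noise$omega[c("uv", "sw")]
    closed <- abs(df[1] - df[2]) / sqrt(sum(om^2))
    expect_equal(chromatic_jnd(x, y, default_noise, channels = c("uv", "sw")),
                 unname(closed), tolerance = 1e-12)
  }

  # the 2-channel restriction is the large-omega limit of the full
  # tetrachromat formula (mw/lw noise -> infinity)
  x <- cone_catch(0.4, 0.3, 0.5, 0.2, 0.3)
  y <- cone_catch(0.2, 0.5, 0.4, 0.3, 0.4)
  big <- 1e8
  lim_noise <- structure(list(
    omega = c(uv = unname(default_noise$omega[["uv"]]),
              sw = unname(default_noise$omega[["sw"]]), mw = big, lw = big),
    omega_dbl = 0.05), class = "receptor_noise")
  expect_equal(chromatic_jnd(x, y, lim_noise),
               chromatic_jnd(x, y, default_noise, channels = c("uv", "sw")),
               tolerance = 1e-6)
})

test_that("quadratic form equals the pairwise oracle for 2-4 channels", {
  set.seed(8)
  for (i in 1:200) {
    x <- random_catch(); y <- random_catch()
    for (ch in list(c("uv", "sw"), c("uv", "sw", "mw"),
                    c("uv", "sw", "mw", "lw"))) {
      expect_equal(chromatic_jnd(x, y, default_noise, channels = ch),
                   rnl_pairwise(x, y, default_noise, channels = ch),
                   tolerance = 1e-10)
    }
  }
})

test_that("dS is a metric on log-catch space and von-Kries invariant", {
  set.seed(9)
  for (i in 1:300) {
    x <- random_catch(); y <- random_catch(); z <- random_catch()
    dxy <- chromatic_jnd(x, y, default_noise)
    dyx <- chromatic_jnd(y, x, default_noise)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_gte(dxy, 0)
    # triangle inequality
    expect_lte(dxy, chromatic_jnd(x, z, default_noise) +
                 chromatic_jnd(z, y, default_noise) + 1e-12)
    # common scaling of both stimuli changes nothing
    s <- exp(rnorm(1))
    xs <- displaced_catch(x, rep(log(s), 4), log(s))
    ys <- displaced_catch(y, rep(log(s), 4), log(s))
    expect_equal(chromatic_jnd(xs, ys, default_noise), dxy,
                 tolerance = 1e-10)
  }
  expect_error(chromatic_jnd(cone_catch(0, 1, 1, 1), cone_catch(1, 1, 1, 1),
                             default_noise), "positive")
})

test_that("achromatic JND behaves", {
  a <- cone_catch(1, 1, 1, 1, 0.5)
  b <- cone_catch(1, 1, 1, 1, 0.5)
  expect_equal(achromatic_jnd(a, b, default_noise), 0)
  nu1 <- receptor_noise(weber_dbl = 1)
  expect_equal(achromatic_jnd(cone_catch(1, 1, 1, 1, exp(1)),
                              cone_catch(1, 1, 1, 1, 1), nu1), 1)
  r <- cone_catch(1, 1, 1, 1, 0.9)
  s <- cone_catch(1, 1, 1, 1, 0.2)
  expect_equal(achromatic_jnd(r, s, default_noise),
               achromatic_jnd(s, r, default_noise))
  expect_error(achromatic_jnd(cone_catch(1, 1, 1, 1), a, default_noise),
               "positive")
  expect_equal(internal_contrast(r, s, default_noise),
               achromatic_jnd(r, s, default_noise))
})

test_that("background contrast uses the mean background", {
  set.seed(10)
  leaves <- replicate(5, random_catch(), simplify = FALSE)
  mean_bg <- colMeans(do.call(rbind, lapply(leaves, unclass)))
  spec <- do.call(cone_catch, as.list(unname(mean_bg)))
  bc <- background_contrast(spec, leaves, default_noise)
  expect_equal(bc$chromatic_jnd, 0, tolerance = 1e-12)
  expect_equal(bc$achromatic_jnd, 0, tolerance = 1e-12)
  expect_equal(nrow(bc$per_background), 5)

  # duplicating a leaf twice leaves the mean-based result unchanged only
  # if the mean is unchanged; duplicating the whole set preserves it
  spec2 <- random_catch()
  bc1 <- background_contrast(spec2, leaves, default_noise)
  bc2 <- background_contrast(spec2, c(leaves, leaves), default_noise)
  expect_equal(bc1$chromatic_jnd, bc2$chromatic_jnd, tolerance = 1e-12)
  expect_error(background_contrast(spec2, list(), default_noise), "empty")
})

test_that("mean-of-catches equals catch-of-mean-spectra (linearity)", {
  wl <- wl_grid()
  viewer <- blue_tit_sensitivities(wl)
  leaves <- generate_reflectance_library(6, seed = 71)
  catches <- lapply(leaves, compute_cone_catch, sensitivities = viewer)
  route1 <- colMeans(do.call(rbind, lapply(catches, unclass)))
  mean_spec <- reflectance_spectrum(
    wl, rowMeans(vapply(leaves, function(s) s$refl, numeric(length(wl)))))
  route2 <- unclass(compute_cone_catch(mean_spec, viewer))
  expect_equal(route1, route2, tolerance = 1e-12)
})

test_that("discriminability classification thresholds", {
  expect_equal(as.character(classify_discriminability(0.5)),
               "indistinguishable")
  expect_equal(as.character(classify_discriminability(3.0)), "marginal")
  expect_equal(as.character(classify_discriminability(10)), "discriminable")
  expect_equal(as.character(classify_discriminability(1.0)),
               "indistinguishable")
  expect_error(classify_discriminability(-1), ">= 0")
  expect_equal(as.character(classify_discriminability(2, thresholds = c(2.5, 4))),
               "indistinguishable")
})
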