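# Linearisation, normalisation and region measurement.

wl <- wl_grid()

test_that("power-law linearisation recovers the sensor exponent", {
  sp <- list(x = flat_reflectance(wl, 0.5))
  for (gamma in c(1, 2.2)) {
    img <- simulate_camera_image(sp, camera_gamma = gamma, noise_sd = 0,
                                 quantise = FALSE)
    model <- fit_linearisation(measure_grey_standards(img))
    expect_equal(unname(model$b), rep(1 / gamma, 4), tolerance = 1e-3)
    expect_equal(unname(model$a), rep(255, 4), tolerance = 1e-2)
  }

  gs <- grey_standard_set(c(0.2, 0.4, 0.8),
                          matrix(c(100, 150, 200), 3, 1,
                                 dimnames = list(NULL, "lw")))
  expect_s3_class(fit_linearisation(gs), "linearisation_model")
  expect_error(
    fit_linearisation(grey_standard_set(c(0.2, 0.4),
                                        matrix(c(100, 150), 2, 1))),
    "3 grey standards")
  # non-monotone measured values
  gs_bad <- grey_standard_set(c(0.2, 0.4, 0.8),
                              matrix(c(100, 90, 200), 3, 1,
                                     dimnames = list(NULL, "lw")))
  expect_error(fit_linearisation(gs_bad), "not strictly increasing")
})

test_that("normalisation recovers reflectance and cancels illumination", {
  sp <- list(a = flat_reflectance(wl, 0.63), b = flat_reflectance(wl, 0.1))
  img <- simulate_camera_image(sp, camera_gamma = 2.2, noise_sd = 0)
  refl <- linearise_and_normalise(img)
  # the 40% standard itself
  std <- measure_region(refl, "std_0.4")
  expect_equal(unname(std$mean), rep(0.40, 4), tolerance = 0.005)
  expect_equal(unname(measure_region(refl, "a")$mean), rep(0.63, 4),
               tolerance = 0.01)

  # halving illumination leaves normalised output unchanged
  dim_img <- simulate_camera_image(sp, camera_gamma = 2.2, noise_sd = 0,
                                   illumination = 0.5)
  dim_refl <- linearise_and_normalise(dim_img)
  expect_equal(measure_region(dim_refl, "a")$mean,
               measure_region(refl, "a")$mean, tolerance = 0.01)

  # saturated normalisation standard is refused (model fitted on the
  # clean frame, applied to an over-exposed one)
  model <- fit_linearisation(measure_grey_standards(img))
  hot <- simulate_camera_image(sp, camera_gamma = 2.2, noise_sd = 0,
                               illumination = 2.6)
  expect_error(linearise_and_normalise(hot, model), "saturated")
})

test_that("round trip recovers region reflectances within 1% for all gammas", {
  targets <- c(r1 = 0.63, r2 = 0.12, r3 = 0.35)
  sp <- lapply(targets, flat_reflectance, wavelengths = wl)
  for (gamma in c(1, 1.8, 2.2)) {
    img <- simulate_camera_image(sp, camera_gamma = gamma, noise_sd = 0)
    cal <- calibrate_image(img)
    for (nm in names(targets)) {
      got <- cal$regions$mean_reflectance[cal$regions$region == nm]
      # within 1% reflectance (absolute: 8-bit quantisation bounds this)
      expect_lt(max(abs(got - targets[[nm]])), 0.01)
    }
    expect_true(all(cal$regions$mean_reflectance >= 0))
  }
})

test_that("region means, pixel counts and trimming behave", {
  sp <- list(u = flat_reflectance(wl, 0.5))
  img <- simulate_camera_image(sp, camera_gamma = 1, noise_sd = 0,
                               quantise = FALSE)
  m <- measure_region(img, "u")
  expect_equal(m$n_pixels, 100)
  expect_equal(unname(m$mean), rep(0.5 * 255, 4), tolerance = 1e-9)

  # half v1 / half v2 mask -> mean of the two
  arr <- img$raw
  lay <- img$layout
  half_mask <- lay$masks$u
  plane <- arr[, , 1]
  idx <- which(half_mask)
  plane[idx[1:50]] <- 100; plane[idx[51:100]] <- 200
  img$raw[, , 1] <- plane
  expect_equal(unname(measure_region(img, "u")$mean[1]), 150)

  # top-percentile trim drops the brightest pixels
  plane[idx] <- 100; plane[idx[76:100]] <- 200
  img$raw[, , 1] <- plane
  expect_equal(unname(measure_region(img, "u", trim_top = 0.3)$mean[1]), 100)
  expect_error(measure_region(img, matrix(FALSE, 2, 2) & FALSE), "empty")
})

test_that("polygon rasterisation agrees with a half-plane oracle", {
  set.seed(8)
  for (rep in 1:5) {
    # random triangle; orient counter-clockwise
    tri <- cbind(runif(3, 1, 40), runif(3, 1, 30))
    a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
    if ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]) < 0) {
      tri <- tri[c(1, 3, 2), ]
      a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
    }
    mask <- polygon_mask(tri, 40, 30)
    side <- function(p, q, x, y) (q[1] - p[1]) * (y - p[2]) - (q[2] - p[2]) * (x - p[1])
    for (px in 1:40) for (py in 1:30) {
      inside <- side(a, b, px, py) > 0 && side(b, c, px, py) > 0 &&
        side(c, a, px, py) > 0
      # boundary pixels may differ by convention; skip near-degenerate ones
      d <- min(abs(side(a, b, px, py)), abs(side(b, c, px, py)),
               abs(side(c, a, px, py)))
      if (d > 1e-6) expect_identical(mask[py, px], inside)
    }
  }
})
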