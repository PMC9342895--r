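test_that("normalization divides by concentration times NATA signal", {
  s <- gaussian_spectrum()
  expect_equal(normalize_spectrum(s, 1, 1)$intensity, s$intensity)
  expect_equal(normalize_spectrum(s, 2, 1)$intensity, s$intensity / 2)
  # scalar oracle: 0.2 * 2.5 = 0.5
  expect_equal(normalize_spectrum(s, 0.2, 2.5)$intensity, s$intensity / 0.5)
})

test_that("double normalization and bad divisors are errors", {
  s <- gaussian_spectrum()
  n <- normalize_spectrum(s, 0.2, 2.5)
  expect_error(normalize_spectrum(n, 1, 1), "already normalized")
  expect_error(normalize_spectrum(s, 0, 1), "positive")
  expect_error(normalize_spectrum(s, 1, -2), "positive")
  expect_error(normalize_spectrum(s), "required")
})

test_that("band integration handles flat, zero, and Gaussian spectra", {
  grid <- seq(300, 400, 1)
  flat <- emission_spectrum(grid, rep(1, length(grid)))
  expect_equal(integrate_band(flat, 320, 370), 50)
  zero <- emission_spectrum(grid, rep(0, length(grid)))
  expect_equal(integrate_band(zero, 320, 370), 0)
  # closed-form oracle for the default analysis band
  g <- gaussian_spectrum(mu = 340, sigma = 15)
  analytic <- gaussian_band_integral(340, 15, 320, 370)
  expect_equal(integrate_band(g, 320, 370), analytic,
               tolerance = 1e-3)
})

test_that("band integration interpolates off-grid edges and is linear", {
  grid <- seq(300, 400, 1)
  flat <- emission_spectrum(grid, rep(2, length(grid)))
  expect_equal(integrate_band(flat, 320.5, 369.25), 2 * (369.25 - 320.5))
  a <- gaussian_spectrum(mu = 335, sigma = 10)
  b <- gaussian_spectrum(mu = 350, sigma = 20)
  combo <- emission_spectrum(grid, 3 * a$intensity + 0.5 * b$intensity)
  expect_equal(integrate_band(combo),
               3 * integrate_band(a) + 0.5 * integrate_band(b),
               tolerance = 1e-9)
})

test_that("band edges outside the spectrum are reported by bound", {
  g <- gaussian_spectrum()
  expect_error(integrate_band(g, 290, 370), "lower band edge")
  expect_error(integrate_band(g, 320, 450), "upper band edge")
  expect_error(integrate_band(g, 370, 320), "lo < hi")
})

test_that("lambda_max of a symmetric band is exact", {
  g <- gaussian_spectrum(mu = 340, sigma = 15)
  expect_equal(find_lambda_max(g)$lambda_max, 340.0, tolerance = 1e-9)
})

test_that("a monotone spectrum is flagged, not assigned a peak", {
  grid <- seq(300, 400, 1)
  mono <- emission_spectrum(grid, rev(seq_along(grid)))
  res <- find_lambda_max(mono)
  expect_identical(res$warning, "edge-maximum")
  expect_true(is.na(res$lambda_max))
})

test_that("lambda_max is robust to noise (dense-grid oracle)", {
  grid <- seq(300, 400, 1)
  skew_band <- function(l) {
    z <- (l - 338) / 20
    exp(-z^2 / 2) * 2 * pnorm(1.5 * z)
  }
  dense <- seq(300, 400, 0.01)
  truth <- dense[which.max(skew_band(dense))]
  clean <- skew_band(grid)
  set.seed(21)
  ests <- vapply(1:200, function(r) {
    noisy <- emission_spectrum(grid, clean + rnorm(length(grid),
                                                   0, 0.01 * max(clean)))
    find_lambda_max(noisy)$lambda_max
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 0.5)
})

test_that("lambda_max is invariant to positive rescaling", {
  g <- gaussian_spectrum(mu = 343.2, sigma = 12)
  l1 <- find_lambda_max(g)$lambda_max
  g5 <- emission_spectrum(g$wavelength_nm, 5 * g$intensity)
  expect_equal(find_lambda_max(g5)$lambda_max, l1, tolerance = 1e-12)
})

test_that("difference spectra subtract pointwise and recover added bands", {
  a <- gaussian_spectrum(mu = 335, sigma = 18)
  expect_true(all(difference_spectrum(a, a)$intensity == 0))
  b <- gaussian_spectrum(mu = 350, sigma = 10)
  apb <- emission_spectrum(a$wavelength_nm, a$intensity + b$intensity)
  expect_equal(difference_spectrum(apb, b)$intensity, a$intensity,
               tolerance = 1e-12)
  # two mixtures differing by one added band
  base <- emission_spectrum(a$wavelength_nm,
                            0.6 * a$intensity + 0.4 * b$intensity)
  extra <- gaussian_spectrum(mu = 342, sigma = 8, amplitude = 0.7)
  with_extra <- emission_spectrum(base$wavelength_nm,
                                  base$intensity + extra$intensity)
  expect_equal(difference_spectrum(with_extra, base)$intensity,
               extra$intensity, tolerance = 1e-12)
})

test_that("difference then integrate commutes with integrate then subtract", {
  a <- gaussian_spectrum(mu = 335, sigma = 18, amplitude = 2)
  b <- gaussian_spectrum(mu = 350, sigma = 10)
  expect_equal(integrate_band(difference_spectrum(a, b)),
               integrate_band(a) - integrate_band(b), tolerance = 1e-9)
})

test_that("mismatched grids fail unless interpolation is requested", {
  a <- gaussian_spectrum(grid = seq(300, 400, 1))
  b <- gaussian_spectrum(grid = seq(300.5, 399.5, 1))
  expect_error(difference_spectrum(a, b), "interpolate")
  d <- difference_spectrum(a, b, interpolate = TRUE)
  expect_true(all(abs(d$intensity) < 0.002))  # interpolation error only
  c_ <- gaussian_spectrum(grid = seq(500, 600, 1))
  expect_error(difference_spectrum(a, c_, interpolate = TRUE), "overlap")
})

test_that("replicate summaries report means and SDs of F and lambda_max", {
  g <- gaussian_spectrum(mu = 340, sigma = 15)
  one <- summarize_f_lambda(list(x = list(g)))
  expect_equal(one$F, integrate_band(g))
  expect_true(is.na(one$F_sd) && is.na(one$lambda_max_sd))

  three <- summarize_f_lambda(list(x = list(g, g, g)))
  expect_equal(three$F_sd, 0)
  expect_equal(three$lambda_max_sd, 0)
  expect_error(summarize_f_lambda(list(x = list())), "empty")
})

test_that("replicate SD of F matches a Monte-Carlo reference within 2x", {
  grid <- seq(300, 400, 1)
  clean <- gaussian_spectrum(mu = 340, sigma = 15, amplitude = 10)$intensity
  sigma <- 0.2
  noisy_spec <- function() {
    emission_spectrum(grid, clean + rnorm(length(grid), 0, sigma))
  }
  set.seed(1)
  mc <- vapply(1:10000, function(i) integrate_band(noisy_spec()), numeric(1))
  ref_sd <- sd(mc)
  # an n = 3 SD is itself noisy (chi with 2 df), so check the typical
  # behaviour over many replicate groups rather than one lucky draw
  group_sds <- vapply(1:50, function(g) {
    summarize_f_lambda(list(g = list(noisy_spec(), noisy_spec(),
                                     noisy_spec())))$F_sd
  }, numeric(1))
  expect_gte(median(group_sds), 0.5 * ref_sd)
  expect_lte(median(group_sds), 2 * ref_sd)
})
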