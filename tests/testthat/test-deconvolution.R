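test_that("noiseless composed traces are inverted exactly", {
  a <- osc_abund()
  truth <- state_fluorescence(canonical_f, offset = 0)
  fit <- fit_state_fluorescence(compose_fapp(truth, a), a)
  expect_equal(fit$f_values, canonical_f, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-8)
})

test_that("the fitter inverts the forward model over random simplex trajectories", {
  set.seed(31)
  for (rep in 1:10) {
    m <- random_osc_model()
    a <- generate_oscillation_abundances(m, seq(0, 3 * m$period, length.out = 61))
    f_true <- setNames(runif(4, -10, 60), names(canonical_f))
    fit <- fit_state_fluorescence(compose_fapp(state_fluorescence(f_true), a), a)
    expect_equal(fit$f_values, f_true, tolerance = 1e-7)
  }
})

test_that("OLS solution matches brute-force normal equations", {
  a <- osc_abund(dt = 1)
  truth <- state_fluorescence(canonical_f)
  tr <- compose_fapp(truth, a, noise_sigma = 1, rng_seed = 3L)
  fit <- fit_state_fluorescence(tr, a)
  X <- abundance_matrix(a)
  beta <- solve(t(X) %*% X, t(X) %*% tr$f_app)
  expect_equal(unname(fit$f_values), as.numeric(beta), tolerance = 1e-10)
})

test_that("a free offset on simplex abundances raises an identifiability error", {
  a <- osc_abund()
  truth <- state_fluorescence(canonical_f, offset = 16)
  tr <- compose_fapp(truth, a)
  expect_error(fit_state_fluorescence(tr, a, with_offset = TRUE),
               "collinear")
})

test_that("an unmodelled constant background is absorbed uniformly into all F_i", {
  a <- osc_abund()
  truth <- state_fluorescence(canonical_f, offset = 16)
  fit <- fit_state_fluorescence(compose_fapp(truth, a), a)
  expect_equal(fit$f_values, canonical_f + 16, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-8)  # the shift is exact, not a lack-of-fit
})

test_that("two-stage offset estimation recovers the background exactly", {
  a <- osc_abund()
  truth <- state_fluorescence(canonical_f, offset = 16.0)
  tr <- compose_fapp(truth, a)
  known_f <- state_fluorescence(canonical_f, offset = 0)
  o <- fit_offset(tr, a, known_f)
  expect_equal(o$offset, 16.0, tolerance = 1e-8)
  # adding a constant c to F_app shifts the offset estimate by exactly c
  tr2 <- tr
  tr2$f_app <- tr$f_app + 3.25
  expect_equal(fit_offset(tr2, a, known_f)$offset, 16.0 + 3.25,
               tolerance = 1e-8)
})

test_that("proportional state trajectories fail loudly", {
  tt <- seq(0, 96, 0.5)
  w <- 0.5 + 0.25 * cos(2 * pi * tt / 24)
  A <- cbind(0.3 * w, 0.3 * w, 0.4 * w, 1 - w)  # first two proportional
  a <- osc_abund()
  a[paste0("A_", KAIC_STATES)] <- A
  truth <- state_fluorescence(canonical_f)
  tr <- compose_fapp(truth, a)
  expect_error(fit_state_fluorescence(tr, a), "collinear")
})

test_that("fitted intensities are invariant to a uniform time shift", {
  a <- osc_abund(dt = 2)
  truth <- state_fluorescence(canonical_f)
  tr <- compose_fapp(truth, a, noise_sigma = 0.5, rng_seed = 9L)
  f1 <- fit_state_fluorescence(tr, a)$f_values
  a2 <- a; a2$time_h <- a$time_h + 13
  tr2 <- fluor_timecourse(tr$time_h + 13, tr$f_app)
  f2 <- fit_state_fluorescence(tr2, a2)$f_values
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  truth <- state_fluorescence(canonical_f)
  a1 <- osc_abund(span = 96, dt = 0.5)
  a4 <- osc_abund(span = 96, dt = 0.125)
  tr1 <- compose_fapp(truth, a1, noise_sigma = 1, rng_seed = 2L)
  tr4 <- compose_fapp(truth, a4, noise_sigma = 1, rng_seed = 2L)
  se1 <- fit_state_fluorescence(tr1, a1)$f_se
  se4 <- fit_state_fluorescence(tr4, a4)$f_se
  ratio <- unname(se1 / se4)
  expect_true(all(ratio > 1.5 & ratio < 2.7))
})

test_that("2 SE intervals cover the truth at the nominal rate", {
  a <- osc_abund()
  truth <- state_fluorescence(canonical_f)
  clean <- compose_fapp(truth, a)
  sigma <- 0.02 * diff(range(clean$f_app))
  n_rep <- 60
  covered <- matrix(FALSE, n_rep, 4)
  for (r in seq_len(n_rep)) {
    tr <- compose_fapp(truth, a, noise_sigma = sigma, rng_seed = 100L + r)
    fit <- fit_state_fluorescence(tr, a)
    covered[r, ] <- abs(fit$f_values - canonical_f) <= 2 * fit$f_se
  }
  expect_true(all(colMeans(covered) >= 0.9))
})

test_that("W419 extraction subtracts per state with quadrature SEs", {
  base <- state_fluorescence(canonical_f, f_se = rep(0.5, 4), construct = "WT")
  same <- extract_w419(base, base)
  expect_equal(unname(same$f_w419), rep(0, 4))
  shifted <- state_fluorescence(canonical_f + 2, f_se = rep(0.5, 4),
                                construct = "F419W")
  unif <- extract_w419(shifted, base)
  expect_equal(unname(unif$f_w419), rep(2, 4))
  expect_equal(unname(unif$f_w419_se), rep(sqrt(0.5), 4), tolerance = 1e-12)
})

test_that("known per-state increments are recovered from two fitted constructs", {
  increments <- c(SpT = 30, pSpT = 2, pST = 12, ST = 28)
  base_f <- c(SpT = 10, pSpT = 6, pST = 8, ST = 10)
  a <- osc_abund()
  sig <- 0.3
  tr_base <- compose_fapp(state_fluorescence(base_f, construct = "WT"), a,
                          noise_sigma = sig, rng_seed = 41L, construct = "WT")
  tr_mut <- compose_fapp(state_fluorescence(base_f + increments,
                                            construct = "F419W"), a,
                         noise_sigma = sig, rng_seed = 42L,
                         construct = "F419W")
  w <- extract_w419(fit_state_fluorescence(tr_mut, a),
                    fit_state_fluorescence(tr_base, a))
  expect_true(all(abs(w$f_w419 - increments) <= 2 * w$f_w419_se))
})

test_that("simulation is constant for pinned states and inverts the fit", {
  m <- phospho_kinetic_model(rates = numeric(0),
                             initial = c(SpT = 0, pSpT = 1, pST = 0, ST = 0))
  a <- generate_autodephos_abundances(m, seq(0, 10, 1))
  sf <- state_fluorescence(canonical_f, offset = 2)
  sim <- simulate_fapp(sf, a)
  expect_equal(sim$f_app, rep(canonical_f[["pSpT"]] + 2, nrow(a)))

  ao <- osc_abund()
  truth <- state_fluorescence(canonical_f)
  x <- compose_fapp(truth, ao)
  fit <- fit_state_fluorescence(x, ao)
  round_trip <- simulate_fapp(fit, ao)
  expect_equal(round_trip$f_app, x$f_app, tolerance = 1e-8)
})

test_that("residual SD of observed minus simulated matches the injected noise", {
  ao <- osc_abund(span = 50, dt = 0.25)   # ~200 points
  truth <- state_fluorescence(canonical_f)
  sigma <- 1.0
  obs <- compose_fapp(truth, ao, noise_sigma = sigma, rng_seed = 17L)
  sim <- simulate_fapp(truth, ao)
  res_sd <- sd(obs$f_app - sim$f_app)
  expect_gte(res_sd, 0.8 * sigma)
  expect_lte(res_sd, 1.2 * sigma)
})

test_that("compare_fit reports RMSD, correlation, and residuals", {
  ao <- osc_abund(dt = 2)
  truth <- state_fluorescence(canonical_f)
  x <- compose_fapp(truth, ao)
  same <- compare_fit(x, x)
  expect_equal(same$rmsd, 0)
  expect_equal(same$pearson_r, 1)
  shifted <- fluor_timecourse(x$time_h, x$f_app + 2.5)
  off <- compare_fit(shifted, x)
  expect_equal(off$rmsd, 2.5, tolerance = 1e-12)
  expect_equal(off$pearson_r, 1, tolerance = 1e-12)
})

test_that("white-noise RMSD follows the sqrt(2) closed form", {
  set.seed(8)
  n <- 1000
  tt <- seq(0, 99.9, length.out = n)
  sigma <- 0.7
  a <- fluor_timecourse(tt, 10 + rnorm(n, 0, sigma))
  b <- fluor_timecourse(tt, 10 + rnorm(n, 0, sigma))
  expect_equal(compare_fit(a, b)$rmsd, sigma * sqrt(2), tolerance = 0.05)
})
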