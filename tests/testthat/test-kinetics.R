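test_that("zero dynamics leave the initial abundances unchanged", {
  m <- phospho_kinetic_model(rates = numeric(0),
                             initial = c(SpT = 0.1, pSpT = 0.2,
                                         pST = 0.3, ST = 0.4))
  a <- generate_autodephos_abundances(m, times = c(0, 1, 7, 30))
  A <- abundance_matrix(a)
  for (i in seq_len(nrow(A))) {
    expect_equal(unname(A[i, ]), c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
  }
})

test_that("ST is absorbing under pure dephosphorylation", {
  m <- phospho_kinetic_model(initial = c(SpT = 0, pSpT = 0, pST = 0, ST = 1))
  a <- generate_autodephos_abundances(m, times = seq(0, 48, by = 4))
  expect_equal(a$A_ST, rep(1, nrow(a)), tolerance = 1e-12)
})

test_that("two-step chain matches the Bateman closed form and a fine-step integrator", {
  k <- 0.2
  m <- phospho_kinetic_model(rates = c("pSpT->pST" = k, "pST->ST" = k),
                             initial = c(SpT = 0, pSpT = 1, pST = 0, ST = 0))
  times <- c(0, 5, 10)
  a <- generate_autodephos_abundances(m, times)

  # equal-rate Bateman solution
  expect_equal(a$A_pSpT, exp(-k * times), tolerance = 1e-10)
  expect_equal(a$A_pST, k * times * exp(-k * times), tolerance = 1e-10)
  expect_equal(a$A_ST, 1 - exp(-k * times) * (1 + k * times), tolerance = 1e-10)

  # independent explicit (RK4) fine-step oracle at dt = 1e-3 h
  dt <- 1e-3
  K <- m$rate_matrix
  deriv <- function(x) as.numeric(K %*% x)
  x <- m$initial
  grid_vals <- list(`0` = x)
  t_now <- 0
  for (step in seq_len(10 / dt)) {
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t_now <- t_now + dt
    if (any(abs(t_now - times) < dt / 2)) {
      grid_vals[[sprintf("%.0f", round(t_now))]] <- x
    }
  }
  for (i in seq_along(times)) {
    expect_equal(unname(abundance_matrix(a)[i, ]),
                 unname(grid_vals[[sprintf("%.0f", times[i])]]),
                 tolerance = 1e-5)
  }
})

test_that("kinetic trajectories conserve total abundance for random rate maps", {
  set.seed(11)
  pairs <- c("ST->SpT", "SpT->pSpT", "pSpT->pST", "pST->ST",
             "SpT->ST", "pSpT->SpT")
  for (rep in 1:10) {
    rates <- setNames(runif(length(pairs), 0, 0.6), pairs)
    init <- runif(4)
    m <- phospho_kinetic_model(rates = rates, initial = init / sum(init))
    a <- generate_autodephos_abundances(m, seq(0, 36, by = 1.5))
    expect_true(all(abs(rowSums(abundance_matrix(a)) - 1) < 1e-9))
    expect_true(all(abundance_matrix(a) > -1e-12))
  }
})

test_that("phosphorylated fraction is non-increasing when ST is absorbing", {
  m <- phospho_kinetic_model()   # default pure-dephosphorylation chain
  a <- generate_autodephos_abundances(m, seq(0, 48, by = 0.25))
  expect_true(all(diff(1 - a$A_ST) <= 1e-12))
})

test_that("kinetic model validation rejects bad input", {
  expect_error(phospho_kinetic_model(rates = c("SpT->ST" = -0.1)),
               "non-negative")
  expect_error(phospho_kinetic_model(initial = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(phospho_kinetic_model(rates = c("foo->ST" = 0.1)), "bad rate")
  m <- phospho_kinetic_model()
  expect_error(generate_autodephos_abundances(m, c(2, 1)), "increasing")
  expect_error(generate_autodephos_abundances(m, c(-1, 1)), ">= 0")
})

test_that("resampling preserves the simplex and refuses extrapolation", {
  a <- osc_abund(dt = 2)
  r <- resample_abundances(a, seq(0, 96, by = 0.5))
  expect_true(all(abs(rowSums(abundance_matrix(r)) - 1) < 1e-12))
  expect_error(resample_abundances(a, seq(0, 100, by = 0.5)), "beyond")
})
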