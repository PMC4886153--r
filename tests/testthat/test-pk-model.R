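test_that("profile is zero with no doses and before the first dose", {
  p <- c(CL = 41.6, Q = 56.8, V1 = 52, V2 = 70.4)
  expect_equal(concentration_profile(p, dose_events(numeric(0)),
                                     c(0, 1, 10)), c(0, 0, 0))
  d <- dose_events(5, rate = 50, duration = 10)
  out <- concentration_profile(p, d, c(0, 2, 4.999, 6))
  expect_equal(out[1:3], c(0, 0, 0))
  expect_gt(out[4], 0)
})

test_that("constant infusion reaches the analytic steady state R0/CL", {
  p <- c(CL = 41.6, Q = 56.8, V1 = 52, V2 = 70.4)
  d <- dose_events(0, rate = 56, duration = 3000)
  expect_equal(concentration_profile(p, d, 2500), 56 / 41.6,
               tolerance = 1e-6)
})

test_that("analytic kernel matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  p <- c(CL = 41.6, Q = 56.8, V1 = 52, V2 = 70.4)
  d <- dose_events(0, rate = 56, duration = 24)
  ts <- c(1, 24, 24.5)
  expect_equal(concentration_profile(p, d, ts), ode_profile(p, d, ts),
               tolerance = 1e-7)

  # random parameter sets and dosing schedules, including boluses and
  # overlapping infusions
  set.seed(401)
  for (k in 1:25) {
    p <- c(CL = runif(1, 5, 80), Q = runif(1, 5, 120),
           V1 = runif(1, 5, 100), V2 = runif(1, 10, 200))
    n_inf <- sample(1:3, 1)
    d <- dose_events(start = runif(n_inf, 0, 30),
                     rate = runif(n_inf, 5, 60),
                     duration = runif(n_inf, 2, 50))
    if (runif(1) < 0.5)
      d <- rbind(d, dose_events(runif(1, 0, 40), amount = runif(1, 20, 200)))
    ts <- sort(runif(8, 0.5, 90))
    a <- concentration_profile(p, d, ts)
    o <- ode_profile(p, d, ts)
    expect_lt(max(abs(a - o) / pmax(abs(o), 1e-8)), 1e-6)
  }
})

test_that("occasion switch preserves compartment state (ODE cross-check)", {
  skip_if_not_installed("deSolve")
  p1 <- c(CL = 41.6, Q = 56.8, V1 = 52, V2 = 70.4)
  p2 <- p1 * c(1.31, 1.02, 1.5, 0.86)
  d <- dose_events(0, rate = 56, duration = 48)
  grid <- dexpk:::.dose_grid(d)
  ts <- c(24, 47.9, 48.2, 49, 52)
  a <- dexpk:::.profile_grid(grid, p1, p2, switch_time = 48, times = ts)
  o <- ode_profile(p1, d, ts, params2 = p2, switch_time = 48)
  expect_equal(a, o, tolerance = 1e-6)
})

test_that("dose superposition and linearity hold to numerical precision", {
  p <- c(CL = 30, Q = 40, V1 = 40, V2 = 90)
  d1 <- dose_events(0, rate = 40, duration = 20)
  d2 <- rbind(dose_events(5, rate = 25, duration = 30),
              dose_events(12, amount = 100))
  ts <- c(1, 6, 13, 20, 30, 40)
  both <- concentration_profile(p, rbind(d1, d2), ts)
  expect_equal(both, concentration_profile(p, d1, ts) +
                 concentration_profile(p, d2, ts), tolerance = 1e-10)
  scaled <- rbind(d1, d2)
  scaled[c("rate", "amount")] <- scaled[c("rate", "amount")] * 3.7
  expect_equal(concentration_profile(p, scaled, ts), 3.7 * both,
               tolerance = 1e-10)
})

test_that("invalid parameters and dose tables are rejected", {
  d <- dose_events(0, rate = 10, duration = 5)
  expect_error(concentration_profile(c(CL = -1, Q = 1, V1 = 1, V2 = 1),
                                     d, 1), "positive")
  expect_error(concentration_profile(c(CL = 1, Q = 1, V1 = 1, V2 = 1),
                                     d, -2), "non-negative")
  expect_error(dose_events(-1, rate = 10, duration = 5), "non-negative")
  expect_error(dose_events(0, rate = 10, duration = 0), "infusion")
  expect_error(dose_events(0), "bolus")
})

test_that("allometric multiplier follows the 70 kg power law", {
  expect_equal(allometric_multiplier(70, 0.75), 1)
  expect_equal(allometric_multiplier(70, 1), 1)
  expect_equal(allometric_multiplier(18.5, 0.75),
               exp(0.75 * log(18.5 / 70)))
  expect_equal(allometric_multiplier(18.5, 1), 18.5 / 70)
  expect_error(allometric_multiplier(0, 1), "positive")
})

test_that("maturation fraction is a Hill function of postmenstrual age", {
  expect_equal(maturation_fraction(42.5, 42.5, 2.45), 0.5)
  expect_equal(maturation_fraction(85, 42.5, 2.45),
               2^2.45 / (1 + 2^2.45), tolerance = 1e-12)
  # step-function limit for steep Hill coefficients
  expect_equal(maturation_fraction(50, 42.5, 500), 1, tolerance = 1e-10)
  expect_lt(maturation_fraction(35, 42.5, 500), 1e-10)
  expect_error(maturation_fraction(-1, 42.5, 2), "positive")

  set.seed(402)
  pma <- sort(exp(runif(1000, log(30), log(600))))
  te50 <- runif(1, 30, 60); hill <- runif(1, 0.5, 6)
  m <- maturation_fraction(pma, te50, hill)
  expect_true(all(m > 0 & m < 1))
  expect_true(all(diff(m) > 0))
})

test_that("individual parameters compose allometry, maturation and fractions", {
  pop <- list(theta = c(CL = 41.6, Q = 56.8, V1 = 52, V2 = 70.4),
              te50 = 42.5, hill = 2.45,
              fractions = c(CL = 1, Q = 1, V1 = 1.5, V2 = 1))
  ref <- list(bw = 70, pma = 1e6) # mature reference subject
  expect_equal(individual_parameters(pop, ref, occasion = 1),
               unlist(pop$theta), tolerance = 1e-6)
  # occasion 2 applies the fractional change exactly
  p2 <- individual_parameters(pop, ref, occasion = 2)
  expect_equal(p2[["V1"]], 52 * 1.5, tolerance = 1e-6)
  expect_equal(p2[["CL"]], 41.6, tolerance = 1e-6)
  # fractions are inactive on occasion 1
  pop_f <- pop; pop_f$fractions <- c(CL = 2, Q = 3, V1 = 4, V2 = 5)
  expect_identical(individual_parameters(pop, ref, occasion = 1),
                   individual_parameters(pop_f, ref, occasion = 1))
  # composition of the allometric and maturation multipliers
  cov <- list(bw = 18.5, pma = 70 * 4.345)
  got <- individual_parameters(pop, cov, occasion = 1)
  expect_equal(got[["CL"]],
               41.6 * allometric_multiplier(18.5, 0.75) *
                 maturation_fraction(70 * 4.345, 42.5, 2.45),
               tolerance = 1e-12)
  expect_equal(got[["V1"]], 52 * allometric_multiplier(18.5, 1),
               tolerance = 1e-12)
  # random effects act multiplicatively on the log scale
  eta <- c(CL = 0.3, Q = -0.2, V1 = 0.1, V2 = 0)
  expect_equal(individual_parameters(pop, cov, eta, occasion = 1),
               got * exp(eta), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(individual_parameters(pop, cov, occasion = 3), "occasion")
})
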