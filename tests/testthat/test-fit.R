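fast_ctl <- function(...) dex_control(n_chains = 2, n_iter = 400,
                                      burn_in = 200, thin = 2, seed = 9, ...)

test_that("control validation and retained-draw accounting", {
  expect_error(dex_control(n_iter = 1000, burn_in = 2000), "exceed")
  expect_error(dex_control(n_iter = 1000, burn_in = 500, thin = 7),
               "multiple")
  # protocol defaults retain 3 x (6000 - 3000) / 3 = 3000 draws
  ct <- dex_control()
  expect_identical(ct$n_chains * (ct$n_iter - ct$burn_in) %/% ct$thin,
                   3000L)
  fit <- suppressWarnings(dex_fit(small_cohort(4, seed = 21),
                                  build_priors(), fast_ctl()))
  expect_length(fit$draws, 2)
  expect_identical(nrow(fit$draws[[1]]), 100L)
  expect_identical(nrow(fit$draws[[2]]), 100L)
})

test_that("identical seeds give identical retained draws", {
  dat <- small_cohort(4, seed = 22)
  pr <- build_priors()
  f1 <- suppressWarnings(dex_fit(dat, pr, fast_ctl()))
  f2 <- suppressWarnings(dex_fit(dat, pr, fast_ctl()))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(dex_fit(dat, pr, dex_control(
    n_chains = 2, n_iter = 400, burn_in = 200, thin = 2, seed = 10)))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("with no observations the posterior reproduces the prior", {
  dat <- small_cohort(6, seed = 2)
  for (j in seq_along(dat)) dat[[j]]$obs <- dat[[j]]$obs[0, ]
  pr <- build_priors()
  fit <- suppressWarnings(dex_fit(dat, pr, dex_control(
    n_chains = 2, n_iter = 1200, burn_in = 600, thin = 2, seed = 5)))
  d <- do.call(rbind, fit$draws)
  lnth <- d[, paste0("ln", c("CL", "Q", "V1", "V2", "TE50", "Hill"))]
  # marginal means and spreads match the prior within Monte-Carlo error
  expect_true(all(abs(colMeans(lnth) - pr$mu_bar) <
                    0.5 * sqrt(pr$Sigma)))
  expect_true(all(apply(lnth, 2, sd) / sqrt(pr$Sigma) > 0.6))
  expect_true(all(apply(lnth, 2, sd) / sqrt(pr$Sigma) < 1.6))
  # nu - 1 ~ Exponential(0.1): mean about 11
  expect_gt(mean(d[, "nu"]), 6)
  expect_lt(mean(d[, "nu"]), 17)
  # fractions ~ lognormal(0, sigma_fP)
  expect_lt(abs(mean(d[, "lnf_V1"])), 0.1)
})

test_that("Gelman-Rubin statistic behaves on known chain configurations", {
  set.seed(55)
  iid <- lapply(1:3, function(i)
    matrix(rnorm(1000), 1000, 1, dimnames = list(NULL, "x")))
  r <- gelman_rubin(iid)
  expect_gt(r$rhat, 0.99)
  expect_lt(r$rhat, 1.05)
  skip_if_not_installed("coda")
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(iid, coda::mcmc)))
  expect_equal(r$rhat, unname(cd$psrf[1, 1]), tolerance = 0.02)

  apart <- lapply(1:3, function(i)
    matrix(rnorm(1000, mean = 10 * i), 1000, 1,
           dimnames = list(NULL, "x")))
  expect_gt(gelman_rubin(apart)$rhat, 1.2)

  flat <- lapply(1:3, function(i)
    matrix(1, 100, 1, dimnames = list(NULL, "x")))
  expect_warning(rc <- gelman_rubin(flat), "constant")
  expect_identical(rc$rhat, 1)

  expect_error(gelman_rubin(iid[1]), "two chains")
})

test_that("posterior summaries are invariant to subject ordering", {
  dat <- small_cohort(6, seed = 30)
  perm <- dexpk:::new_dex_data(dat[c(4, 1, 6, 2, 5, 3)])
  pr <- build_priors()
  ctl <- dex_control(n_chains = 2, n_iter = 1000, burn_in = 500, thin = 1,
                     seed = 77)
  f1 <- suppressWarnings(dex_fit(dat, pr, ctl))
  f2 <- suppressWarnings(dex_fit(perm, pr, ctl))
  m1 <- colMeans(do.call(rbind, f1$draws))
  m2 <- colMeans(do.call(rbind, f2$draws))
  keep <- c(paste0("ln", c("CL", "Q", "V1", "V2", "TE50", "Hill")),
            "sigma_C")
  expect_true(all(abs(m1[keep] - m2[keep]) < 0.12))
})

test_that("DIC collapses to the plug-in deviance for a point-mass posterior", {
  fit <- suppressWarnings(dex_fit(small_cohort(4, seed = 23),
                                  build_priors(), fast_ctl()))
  pt <- fit
  for (ch in seq_along(pt$draws)) # same single draw in every chain
    pt$draws[[ch]] <- pt$draws[[1]][rep(5, nrow(pt$draws[[1]])), ]
  d <- dic(pt)
  expect_equal(d$pD, 0, tolerance = 1e-6)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-6)
  expect_equal(unname(d$Dbar), unname(-2 * pt$draws[[1]][1, "loglik"]),
               tolerance = 1e-8)
})

test_that("fraction-effect probabilities match closed-form oracles", {
  fit <- suppressWarnings(dex_fit(small_cohort(3, seed = 24),
                                  build_priors(), fast_ctl()))
  syn <- fit
  n <- nrow(syn$draws[[1]])
  for (ch in seq_along(syn$draws)) {
    syn$draws[[ch]][, "lnf_CL"] <- 0          # all draws exactly 1
    syn$draws[[ch]][, "lnf_Q"] <- log(1.5)    # all draws exactly 1.5
  }
  pr <- fraction_effect_probability(syn, threshold = 0.2)
  expect_identical(unname(pr["CL"]), 0)
  expect_identical(unname(pr["Q"]), 1)

  # lognormal(ln 1.31, 0.28^2) draws: tail mass from the normal CDF
  set.seed(91)
  z <- rnorm(2 * n * length(syn$draws), log(1.31), 0.28)
  for (ch in seq_along(syn$draws))
    syn$draws[[ch]][, "lnf_V1"] <-
      z[seq((ch - 1) * n + 1, ch * n)]
  pr2 <- fraction_effect_probability(syn, threshold = 0.2)
  expected <- 1 - pnorm(log(1.2), log(1.31), 0.28) +
    pnorm(-log(1.2), log(1.31), 0.28)
  expect_equal(unname(pr2["V1"]), expected, tolerance = 0.08)
  # one-sided variant
  pr3 <- fraction_effect_probability(syn, threshold = 0.2,
                                     two_sided = FALSE)
  expect_lte(pr3["V1"], pr2["V1"])
})

test_that("a tight fraction prior pins the occasion shifts at one", {
  dat <- small_cohort(5, seed = 25)
  pr <- build_priors(sigma_fP = 0.01)
  fit <- suppressWarnings(dex_fit(dat, pr, fast_ctl()))
  lnf <- do.call(rbind, fit$draws)[, paste0("lnf_", c("CL", "Q", "V1", "V2"))]
  expect_lt(quantile(abs(lnf), 0.95), 0.03)
})

test_that("fraction sensitivity tabulates DIC and bias over the prior grid", {
  dat <- small_cohort(5, seed = 26)
  tab <- suppressWarnings(fraction_sensitivity(
    dat, build_priors(), sigma_fP_grid = c(0.01, 0.4),
    control = dex_control(n_chains = 2, n_iter = 300, burn_in = 200,
                          thin = 1, seed = 3)))
  expect_s3_class(tab, "dex_sensitivity")
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("sigma_fP", "DIC", "MDPE", "MDAPE", "f_V1") %in%
                    names(tab)))
  expect_true(all(is.finite(tab$DIC)))
  expect_error(fraction_sensitivity(dat, build_priors(),
                                    sigma_fP_grid = c(-1, 0.2)), "positive")
})
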