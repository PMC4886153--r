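test_that("MDPE/MDAPE follow the per-subject median definition", {
  # perfect predictions
  pe0 <- prediction_errors(c(1, 2, 3), c(1, 2, 3), c("a", "a", "b"))
  expect_identical(pe0$MDPE, 0)
  expect_identical(pe0$MDAPE, 0)

  # three subjects engineered to have median PEs of -10, 5, 20
  pred <- rep(100, 6)
  obs <- c(90, 90, 105, 105, 120, 120)
  subj <- c(1, 1, 2, 2, 3, 3)
  pe <- prediction_errors(obs, pred, subj)
  expect_equal(sort(pe$per_subject$median_pe), c(-10, 5, 20))
  expect_equal(pe$MDPE, 5)
  expect_equal(pe$MDAPE, 10)
})

test_that("prediction errors are scale-consistent and guard bad inputs", {
  set.seed(61)
  obs <- rlnorm(30); pred <- rlnorm(30); subj <- rep(1:5, each = 6)
  a <- prediction_errors(obs, pred, subj)
  b <- prediction_errors(obs * 7.3, pred * 7.3, subj)
  expect_equal(a$MDPE, b$MDPE)
  expect_equal(a$MDAPE, b$MDAPE)
  expect_warning(bad <- prediction_errors(obs, replace(pred, 3, -1), subj),
                 "non-positive")
  expect_identical(bad$n_excluded, 1L)
  expect_error(prediction_errors(1:3, 1:2, 1:3), "equal length")
})

test_that("population prediction errors on a correct-model fit show no gross bias", {
  # Generating values at the prior centres, so the check is not confounded
  # by prior-data conflict. MDPE is a median-of-medians with substantial
  # cohort-level sampling spread even at the true parameters, so the bias
  # check is paired: on the same cohort, the fitted population MDPE must
  # track the MDPE computed with the generating parameters.
  tr <- true_parameters(theta = c(CL = 42.1, Q = 78.3, V1 = 56.3, V2 = 69),
                        te50 = 44.5, hill = 2.56,
                        fractions = c(CL = 1, Q = 1, V1 = 1, V2 = 1),
                        iiv_cv = c(CL = 30.9, Q = 37, V1 = 61.3, V2 = 47),
                        outlier_fraction = 0)
  dat <- generate_dataset(cohort_config(n_subjects = 20, seed = 88),
                          truth = tr)
  pop <- list(theta = tr$theta, te50 = tr$te50, hill = tr$hill,
              fractions = tr$fractions)
  obs <- c(); prd <- c(); id <- c()
  for (s in dat) {
    p1 <- individual_parameters(pop, list(bw = s$bw, pma = s$pma),
                                occasion = 1)
    p2 <- individual_parameters(pop, list(bw = s$bw, pma = s$pma),
                                occasion = 2)
    g <- dexpk:::.dose_grid(s$doses)
    prd <- c(prd, dexpk:::.profile_grid(g, p1, p2, g$cessation, s$obs$time))
    obs <- c(obs, s$obs$conc); id <- c(id, rep(s$id, nrow(s$obs)))
  }
  pe_truth <- prediction_errors(obs, prd, id)

  fit <- suppressWarnings(dex_fit(dat, build_priors(), dex_control(
    n_chains = 2, n_iter = 1500, burn_in = 750, thin = 1, seed = 17)))
  pe_fit <- prediction_errors_fit(fit)
  expect_lt(abs(pe_fit$MDPE - pe_truth$MDPE), 10)
  expect_gte(pe_fit$MDAPE, 0)
})

test_that("PPC bands are ordered and sized by the protocol bins", {
  ppc <- posterior_predictive_check(recovery_fit(), n_rep = 100, seed = 4)
  expect_s3_class(ppc, "dex_ppc")
  # percentile ordering inside every bin, observed and predicted
  for (b in unique(ppc$bin)) {
    d <- ppc[ppc$bin == b, ]
    d <- d[order(d$percentile), ] # p10, p50, p90
    expect_true(!is.unsorted(d$observed))
    expect_true(!is.unsorted(d$pred_med))
    expect_true(all(d$pred_lo <= d$pred_hi))
  }
  expect_true(all(ppc$occasion %in% 1:2))
  expect_true(all(ppc$n_obs >= 3))
})

test_that("PPC flags gross misfit when observations are doubled", {
  fit <- recovery_fit()
  shifted <- fit
  shifted$prep$obs_log_all <- fit$prep$obs_log_all + log(2)
  ppc <- posterior_predictive_check(shifted, n_rep = 100, seed = 4)
  p50 <- ppc[ppc$percentile == "p50", ]
  expect_gt(mean(p50$outside), 0.5)
})

test_that("eta-covariate screen recovers planted signals and stays null otherwise", {
  fit <- suppressWarnings(dex_fit(
    small_cohort(12, seed = 33), build_priors(),
    dex_control(n_chains = 2, n_iter = 300, burn_in = 200, thin = 1,
                seed = 13)))
  ns <- fit$prep$n
  syn <- fit
  set.seed(71)
  bw <- vapply(fit$prep$subs, `[[`, 0, "bw")
  # plant: eta_CL proportional to ln(weight); eta_Q pure noise
  for (ch in seq_along(syn$draws)) {
    n <- nrow(syn$draws[[ch]])
    for (j in seq_len(ns)) {
      syn$draws[[ch]][, paste0("eta_CL[", j, "]")] <- 2 * log(bw[j] / 20)
      syn$draws[[ch]][, paste0("eta_Q[", j, "]")] <- rnorm(n, 0, 0.01) +
        rnorm(1, 0, 0.3)
    }
  }
  scr <- eta_covariate_screen(syn, threshold = 0.4)
  got <- scr[scr$eta == "CL" & scr$covariate == "weight", ]
  expect_gt(got$statistic, 0.9)
  expect_true(got$flagged)
  null_row <- scr[scr$eta == "Q" & scr$covariate == "prism", ]
  expect_lt(abs(null_row$statistic), 0.75)

  # identical sex distributions for eta -> near-zero standardised difference
  for (ch in seq_along(syn$draws))
    for (j in seq_len(ns))
      syn$draws[[ch]][, paste0("eta_V2[", j, "]")] <- (j %% 2) * 0.4
  sexes <- vapply(fit$prep$subs, `[[`, "", "sex")
  if (length(unique(sexes)) == 2) {
    scr2 <- eta_covariate_screen(syn)
    expect_true(is.finite(
      scr2$statistic[scr2$eta == "V2" & scr2$covariate == "sex"]))
  }
})

test_that("constant covariates are reported as undefined associations", {
  fit <- suppressWarnings(dex_fit(
    small_cohort(4, seed = 34), build_priors(),
    dex_control(n_chains = 2, n_iter = 200, burn_in = 100, thin = 1,
                seed = 14)))
  flat <- fit
  for (j in seq_len(flat$prep$n)) flat$prep$subs[[j]]$prism <- 0
  scr <- eta_covariate_screen(flat)
  expect_true(all(is.na(
    scr$statistic[scr$covariate == "prism"])))
  expect_true(all(!scr$flagged[scr$covariate == "prism"]))
})

test_that("null screen on correct-model data flags no systematic covariate", {
  # allometry and maturation are part of the generator and the model, so a
  # correct-model fit should leave no residual eta-covariate structure
  scr <- eta_covariate_screen(recovery_fit())
  cont <- scr[scr$type == "spearman", ]
  expect_lt(mean(cont$flagged), 0.25)
  expect_lt(median(abs(cont$statistic)), 0.4)
})
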