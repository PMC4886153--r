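# Internal model machinery shared by the public likelihood functions and the
# sampler: per-subject dose grids, prediction under (ln theta, ln f, eta),
# and the Student-t observation density on log concentrations.

.ALLO_K <- c(CL = 0.75, Q = 0.75, V1 = 1, V2 = 1)

# Precompute everything about a dataset that does not depend on parameters.
# Observations at or before the first dose cannot have positive predictions
# and are excluded with a warning (pre-dose baseline samples).
.prep_subjects <- function(data, warn = TRUE, drop_predose = TRUE) {
  stopifnot(inherits(data, "dex_data"))
  n_drop <- 0L
  subs <- lapply(data, function(s) {
    grid <- .dose_grid(s$doses)
    if (nrow(s$doses) == 0) .dex_stop("subject ", s$id, " has no dose events")
    first_dose <- min(s$doses$start)
    obs <- s$obs
    if (drop_predose && nrow(obs) && any(obs$time <= first_dose)) {
      n_drop <<- n_drop + sum(obs$time <= first_dose)
      obs <- obs[obs$time > first_dose, , drop = FALSE]
    }
    obs <- obs[order(obs$time), , drop = FALSE]
    list(id = s$id, grid = grid, switch_time = grid$cessation,
         obs_t = obs$time, obs_log = log(obs$conc), occ = obs$occasion,
         lbw = log(s$bw / .REF_BW), pma = s$pma, bw = s$bw, age = s$age,
         sex = s$sex, prism = s$prism,
         duration = if (is.finite(grid$cessation))
           grid$cessation - min(s$doses$start) else NA_real_,
         total_dose = sum(s$doses$amount))
  })
  if (n_drop > 0 && warn)
    warning(n_drop, " observation(s) at or before the first dose excluded ",
            "from the likelihood (zero predicted concentration)")
  idx_end <- cumsum(vapply(subs, function(s) length(s$obs_t), 0L))
  list(subs = subs, n = length(subs),
       obs_log_all = unlist(lapply(subs, `[[`, "obs_log")),
       idx_start = c(1L, head(idx_end, -1) + 1L), idx_end = idx_end)
}

# individual parameter sets (occasion 1 and 2) for one prepared subject
.subject_pars <- function(s, lnth, lnf, eta_j) {
  mf <- 1 / (1 + exp(exp(lnth[6]) * (lnth[5] - log(s$pma)))) # maturation
  lp <- lnth[1:4] + .ALLO_K * s$lbw + eta_j
  lp[1] <- lp[1] + log(mf)
  p1 <- exp(lp)
  list(p1 = p1, p2 = p1 * exp(lnf))
}

.subject_pred <- function(s, lnth, lnf, eta_j) {
  pp <- .subject_pars(s, lnth, lnf, eta_j)
  .cpp_pk_profile(s$grid$seg_t, s$grid$seg_rate, s$grid$seg_bolus,
                  pp$p1, pp$p2, s$switch_time, s$obs_t)
}

# total t log-likelihood from a flat log-residual vector
.t_ll <- function(resid, sigma, nu) {
  n <- length(resid)
  if (n == 0) return(0)
  n * (lgamma((nu + 1) / 2) - lgamma(nu / 2) -
         0.5 * log(nu * pi * sigma^2)) -
    0.5 * (nu + 1) * sum(log1p((resid / sigma)^2 / nu))
}

#' Robust observation log-likelihood
#'
#' Sum over all observations of the Student-t log density on the natural-log
#' concentration scale: location `ln C_pred`, scale `sigma_C`, degrees of
#' freedom `nu`. Heavy tails (small `nu`) make the fit robust to outlying
#' concentration measurements. Returns `-Inf` (a rejected state, not an
#' error) when the model predicts a non-positive concentration at an
#' observation time.
#'
#' @param theta named natural-scale typical values
#'   (`CL`, `Q`, `V1`, `V2`, `TE50`, `Hill`)
#' @param fractions named occasion-2 multipliers (`CL`, `Q`, `V1`, `V2`);
#'   all 1 for no occasion shift
#' @param etas matrix of per-subject log-scale random effects (subjects in
#'   rows, columns `CL`, `Q`, `V1`, `V2`), or `NULL` for all-zero
#' @param residual list with `sigma_C` (> 0) and `nu` (> 1)
#' @param data a [dex_data()] object
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(theta, fractions = c(CL = 1, Q = 1, V1 = 1, V2 = 1),
                           etas = NULL, residual, data) {
  prep <- .prep_subjects(data, warn = FALSE, drop_predose = FALSE)
  th <- unlist(theta)[.THETA]
  if (anyNA(th) || any(th <= 0)) .dex_stop("theta must be positive and complete")
  if (residual$sigma_C <= 0 || residual$nu <= 1)
    .dex_stop("need sigma_C > 0 and nu > 1")
  lnth <- log(th)
  lnf <- log(unlist(fractions)[.PK_PARS])
  if (is.null(etas)) etas <- matrix(0, prep$n, 4)
  ll <- 0
  for (j in seq_len(prep$n)) {
    s <- prep$subs[[j]]
    if (!length(s$obs_t)) next
    pred <- .subject_pred(s, lnth, lnf, etas[j, ])
    lj <- .cpp_t_loglik(pred, s$obs_log, residual$sigma_C, residual$nu)
    if (!is.finite(lj)) return(-Inf)
    ll <- ll + lj
  }
  ll
}

#' Joint log prior density
#'
#' The informative hierarchical prior: multivariate normal on `ln theta`
#' (diagonal `Sigma`), Wishart on the inverse between-subject covariance
#' `Omega^-1` (scale `rho * Omega0`, df `rho`, BUGS parameterisation),
#' multivariate normal `MVN(0, Omega)` on each subject's random-effect
#' vector, uniform on the residual scale `sigma_C`, shifted exponential on
#' `nu - 1`, and `N(0, sigma_fP^2)` on each log occasion fraction. States
#' outside the support return `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param Omega between-subject covariance matrix (4 x 4, symmetric
#'   positive-definite)
#' @param priors a [build_priors()] object
#' @return scalar log prior density
#' @export
log_prior <- function(theta, fractions = c(CL = 1, Q = 1, V1 = 1, V2 = 1),
                      etas = NULL, Omega, residual, priors) {
  th <- unlist(theta)[.THETA]
  if (anyNA(th) || any(th <= 0)) return(-Inf)
  lnth <- log(th)
  lp <- sum(dnorm(lnth, priors$mu_bar, sqrt(priors$Sigma), log = TRUE))
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  lp <- lp + .dwish_log(chol2inv(ch), priors$rho, priors$Omega0)
  if (!is.null(etas)) {
    etas <- rbind(etas)
    Oinv <- chol2inv(ch)
    ldet <- 2 * sum(log(diag(ch)))
    q <- rowSums((etas %*% Oinv) * etas)
    lp <- lp + sum(-0.5 * (4 * log(2 * pi) + ldet + q))
  }
  b <- priors$sigmaC_bounds
  if (residual$sigma_C < b[1] || residual$sigma_C > b[2]) return(-Inf)
  lp <- lp - log(b[2] - b[1])
  if (residual$nu <= 1) return(-Inf)
  lp <- lp + log(priors$nu_rate) - priors$nu_rate * (residual$nu - 1)
  lnf <- log(unlist(fractions)[.PK_PARS])
  lp + sum(dnorm(lnf, 0, priors$sigma_fP, log = TRUE))
}

# log density of Wishart(scale rho*Omega0, df rho) [BUGS form] at W = Omega^-1,
# i.e. rWishart's Wishart(df = rho, Sigma = (rho*Omega0)^-1)
.dwish_log <- function(W, rho, Omega0) {
  d <- nrow(W)
  chW <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(chW)) return(-Inf)
  ldetW <- 2 * sum(log(diag(chW)))
  S <- rho * Omega0 # = V^-1
  ldetV <- -2 * sum(log(diag(chol(S))))
  0.5 * (rho - d - 1) * ldetW - 0.5 * sum(S * W) -
    0.5 * rho * d * log(2) - 0.5 * rho * ldetV - .lmvgamma(d, rho / 2)
}

.lmvgamma <- function(d, a)
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
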