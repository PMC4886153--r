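#' @export
print.dex_fit <- function(x, ...) {
  ct <- x$control
  cat("Bayesian two-compartment population PK fit (dexmedetomidine)\n")
  cat(sprintf("  %d subjects, %d observations; %d chains x %d iterations ",
              x$prep$n, length(x$prep$obs_log_all),
              ct$n_chains, ct$n_iter))
  cat(sprintf("(burn-in %d, thin %d) -> %d retained draws\n",
              ct$burn_in, ct$thin,
              ct$n_chains * (ct$n_iter - ct$burn_in) %/% ct$thin))
  cat(sprintf("  max Rhat %.3f (%s); DIC %.1f (pD %.1f)\n",
              max(x$rhat$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged",
              x$dic$DIC, x$dic$pD))
  th <- coef(x)
  cat("  theta:", paste(sprintf("%s=%.3g", names(th$theta), th$theta),
                        collapse = ", "), "\n")
  if (x$control$include_fractions)
    cat("  occasion fractions:",
        paste(sprintf("%s=%.3g", names(th$fractions), th$fractions),
              collapse = ", "), "\n")
  invisible(x)
}

#' Posterior means of the model parameters
#'
#' @param object a [dex_fit()] result
#' @param ... unused
#' @return list with natural-scale posterior means: `theta` (typical values
#'   `CL`, `Q`, `V1`, `V2`, `TE50`, `Hill`), `fractions` (occasion-2
#'   multipliers), `sigma_C`, `nu`, and `Omega` (posterior mean covariance)
#' @export
coef.dex_fit <- function(object, ...) {
  d <- do.call(rbind, object$draws)
  om <- matrix(colMeans(d[, grep("^Omega\\[", colnames(d))]), 4, 4,
               dimnames = list(.PK_PARS, .PK_PARS))
  list(theta = setNames(colMeans(exp(d[, paste0("ln", .THETA)])), .THETA),
       fractions = setNames(colMeans(exp(d[, paste0("lnf_", .PK_PARS)])),
                            .PK_PARS),
       sigma_C = unname(mean(d[, "sigma_C"])),
       nu = unname(mean(d[, "nu"])),
       Omega = om)
}

#' Posterior summary of a fitted model
#'
#' Natural-scale posterior means and equal-tailed 90% credible intervals for
#' the typical values and occasion fractions, between-subject variability as
#' %CV with the `Q`-`V1` correlation, the residual model, convergence and
#' DIC.
#'
#' @param object a [dex_fit()] result
#' @param prob credible-interval mass (default 0.90)
#' @param ... unused
#' @return object of class `summary.dex_fit`
#' @export
summary.dex_fit <- function(object, prob = 0.90, ...) {
  d <- do.call(rbind, object$draws)
  a <- (1 - prob) / 2
  sum_nat <- function(cols, names_out) {
    x <- exp(d[, cols, drop = FALSE])
    data.frame(parameter = names_out, mean = colMeans(x),
               lo = apply(x, 2, quantile, a),
               hi = apply(x, 2, quantile, 1 - a), row.names = NULL)
  }
  theta <- sum_nat(paste0("ln", .THETA), .THETA)
  fractions <- sum_nat(paste0("lnf_", .PK_PARS), paste0("f_", .PK_PARS))
  omd <- d[, paste0("Omega[", 1:4, ",", 1:4, "]")]
  iiv <- data.frame(parameter = .PK_PARS,
                    cv_percent = 100 * sqrt(exp(colMeans(omd)) - 1),
                    row.names = NULL)
  corQV1 <- mean(d[, "Omega[2,3]"] / sqrt(d[, "Omega[2,2]"] *
                                            d[, "Omega[3,3]"]))
  resid <- data.frame(parameter = c("sigma_C", "nu"),
                      mean = c(mean(d[, "sigma_C"]), mean(d[, "nu"])),
                      lo = c(quantile(d[, "sigma_C"], a),
                             quantile(d[, "nu"], a)),
                      hi = c(quantile(d[, "sigma_C"], 1 - a),
                             quantile(d[, "nu"], 1 - a)), row.names = NULL)
  structure(list(theta = theta, fractions = fractions, iiv = iiv,
                 cor_Q_V1 = corQV1, residual = resid, prob = prob,
                 rhat_max = max(object$rhat$rhat, na.rm = TRUE),
                 converged = object$converged, dic = object$dic,
                 include_fractions = object$control$include_fractions),
            class = "summary.dex_fit")
}

#' @export
print.summary.dex_fit <- function(x, digits = 3, ...) {
  ci <- sprintf("%d%% CrI", round(100 * x$prob))
  fmt <- function(tab) {
    tab$mean <- signif(tab$mean, digits)
    tab[[ci]] <- sprintf("(%s-%s)", signif(tab$lo, digits),
                         signif(tab$hi, digits))
    tab[, c("parameter", "mean", ci)]
  }
  cat("Typical values (70 kg reference):\n")
  print(fmt(x$theta), row.names = FALSE)
  if (x$include_fractions) {
    cat("\nOccasion-2 fractional changes:\n")
    print(fmt(x$fractions), row.names = FALSE)
  }
  cat("\nBetween-subject variability (%CV):",
      paste(sprintf("%s %.0f", x$iiv$parameter, x$iiv$cv_percent),
            collapse = ", "), "\n")
  cat(sprintf("Posterior mean cor(Q, V1): %.2f\n", x$cor_Q_V1))
  cat("\nResidual t model:\n")
  print(fmt(x$residual), row.names = FALSE)
  cat(sprintf("\nmax Rhat %.3f (%s); DIC %.1f (Dbar %.1f, pD %.1f)\n",
              x$rhat_max, if (x$converged) "converged" else "NOT converged",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}

#' Model-predicted concentrations at the observation times
#'
#' `"population"` predictions use the posterior-mean typical values with
#' each subject's covariates and occasion (random effects set to zero) --
#' the convention used for prediction-error summaries. `"individual"`
#' predictions additionally use each subject's posterior-mean random
#' effects.
#'
#' @param object a [dex_fit()] result
#' @param type `"population"` or `"individual"`
#' @param newdata optional [dex_data()] object (defaults to the fitted data)
#' @param ... unused
#' @return data frame with `id`, `time`, `occasion`, `observed`, `predicted`
#' @export
predict.dex_fit <- function(object, type = c("population", "individual"),
                            newdata = NULL, ...) {
  type <- match.arg(type)
  prep <- if (is.null(newdata)) object$prep else .prep_subjects(newdata)
  if (!is.null(newdata) && type == "individual")
    .dex_stop("individual predictions are only defined for the fitted data")
  d <- do.call(rbind, object$draws)
  pm <- colMeans(d)
  lnth <- pm[paste0("ln", .THETA)]
  lnf <- pm[paste0("lnf_", .PK_PARS)]
  rows <- lapply(seq_len(prep$n), function(j) {
    s <- prep$subs[[j]]
    if (!length(s$obs_t)) return(NULL)
    eta_j <- if (type == "individual")
      pm[paste0("eta_", .PK_PARS, "[", j, "]")] else rep(0, 4)
    data.frame(id = s$id, time = s$obs_t, occasion = s$occ,
               observed = exp(s$obs_log),
               predicted = .subject_pred(s, lnth, lnf, eta_j))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
residuals.dex_fit <- function(object, type = c("individual", "population"),
                              ...) {
  type <- match.arg(type)
  pr <- predict(object, type = type)
  setNames(log(pr$observed) - log(pr$predicted),
           paste0(pr$id, "@", signif(pr$time, 6)))
}

#' Posterior predictive replicates of the study
#'
#' For each replicate one retained draw is selected at random and every
#' subject's observations are re-simulated under that draw -- the subject's
#' own posterior random effects, dosing and sampling design -- with fresh
#' Student-t residual noise. This is the "individual prediction" replicate
#' set underlying the posterior predictive check.
#'
#' @param object a [dex_fit()] result
#' @param nsim number of replicate datasets
#' @param seed optional integer seed (local to this call)
#' @param ... unused
#' @return list of `nsim` data frames with `id`, `time`, `occasion`, `conc`
#' @export
simulate.dex_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  d <- do.call(rbind, object$draws)
  prep <- object$prep
  picks <- sample.int(nrow(d), nsim, replace = nsim > nrow(d))
  lapply(picks, function(k) {
    lnth <- d[k, paste0("ln", .THETA)]
    lnf <- d[k, paste0("lnf_", .PK_PARS)]
    sigma <- d[k, "sigma_C"]; nu <- d[k, "nu"]
    rows <- lapply(seq_len(prep$n), function(j) {
      s <- prep$subs[[j]]
      if (!length(s$obs_t)) return(NULL)
      eta_j <- d[k, paste0("eta_", .PK_PARS, "[", j, "]")]
      pred <- .subject_pred(s, lnth, lnf, eta_j)
      data.frame(id = s$id, time = s$obs_t, occasion = s$occ,
                 conc = exp(log(pred) + sigma * rt(length(pred), nu)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Plot a fitted model
#'
#' `type = "fit"` draws observed vs predicted concentrations (log-log);
#' `type = "trace"` draws MCMC traces of the main scalar parameters per
#' chain.
#'
#' @param x a [dex_fit()] result
#' @param type `"fit"` or `"trace"`
#' @param pars parameters to trace (default the typical values)
#' @param ... passed to the base plotting functions
#' @export
plot.dex_fit <- function(x, type = c("fit", "trace"),
                         pars = paste0("ln", .THETA), ...) {
  type <- match.arg(type)
  if (type == "fit") {
    pr <- predict(x, type = "individual")
    graphics::plot(pr$predicted, pr$observed, log = "xy",
                   xlab = "individual predicted (ng/mL)",
                   ylab = "observed (ng/mL)", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                         mar = c(3, 4, 1, 1))
    on.exit(graphics::par(old))
    for (p in pars) {
      ylim <- range(vapply(x$draws, function(ch) range(ch[, p]),
                           numeric(2)))
      graphics::plot(x$draws[[1]][, p], type = "l", ylab = p, ylim = ylim,
                     xlab = "retained draw", ...)
      for (ch in seq_along(x$draws)[-1])
        graphics::lines(x$draws[[ch]][, p], col = ch)
    }
  }
  invisible(x)
}
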