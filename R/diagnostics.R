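#' Prediction-error summary (MDPE / MDAPE)
#'
#' The prediction error of each observation is
#' `PE = 100 * (observed - predicted) / predicted` (%), summarised as a
#' median per subject; the median prediction error `MDPE` (bias) and median
#' absolute prediction error `MDAPE` (inaccuracy) are then medians across
#' the per-subject medians. Observations with non-positive predictions are
#' excluded with a warning.
#'
#' @param observed,predicted paired observation and population-prediction
#'   vectors (same length, same units)
#' @param subject subject identifier per observation
#' @return list of class `dex_pe` with `per_subject` (data frame of
#'   per-subject median PEs), `MDPE`, `MDAPE` and `n_excluded`
#' @export
prediction_errors <- function(observed, predicted, subject) {
  if (length(observed) != length(predicted) ||
      length(observed) != length(subject))
    .dex_stop("observed, predicted and subject must have equal length")
  bad <- !(predicted > 0)
  if (any(bad)) {
    warning(sum(bad), " observation(s) with non-positive prediction excluded")
    observed <- observed[!bad]; predicted <- predicted[!bad]
    subject <- subject[!bad]
  }
  pe <- 100 * (observed - predicted) / predicted
  med <- vapply(split(pe, subject), median, 0)
  per_subject <- data.frame(subject = names(med), median_pe = unname(med),
                            row.names = NULL)
  structure(list(per_subject = per_subject,
                 MDPE = median(med), MDAPE = median(abs(med)),
                 n_excluded = sum(bad)),
            class = "dex_pe")
}

#' @export
print.dex_pe <- function(x, ...) {
  cat(sprintf("MDPE %.2f%% (bias), MDAPE %.2f%% (inaccuracy), %d subjects\n",
              x$MDPE, x$MDAPE, nrow(x$per_subject)))
  invisible(x)
}

#' @describeIn prediction_errors population-prediction errors of a fitted
#'   model (random effects at zero, posterior-mean typical values)
#' @param fit a [dex_fit()] result
#' @export
prediction_errors_fit <- function(fit) {
  pr <- predict(fit, type = "population")
  prediction_errors(pr$observed, pr$predicted, pr$id)
}

# protocol nominal sampling times (h); occasion 2 is time since cessation
.NOMINAL_OCC1 <- c(1, 4, 8, 12, 16, 20, 24)
.NOMINAL_OCC2 <- c(0, 5 / 60, 10 / 60, 20 / 60, 1, 2, 4, 6)

# assign each observation to its nearest protocol bin within its occasion
.assign_bins <- function(prep) {
  rows <- lapply(prep$subs, function(s) {
    if (!length(s$obs_t)) return(NULL)
    tt <- ifelse(s$occ == 2, s$obs_t - s$switch_time, s$obs_t)
    nominal <- vapply(seq_along(tt), function(i) {
      grid <- if (s$occ[i] == 2) .NOMINAL_OCC2 else .NOMINAL_OCC1
      grid[which.min(abs(grid - tt[i]))]
    }, 0)
    data.frame(id = s$id, occasion = s$occ, nominal = nominal)
  })
  do.call(rbind, rows)
}

#' Binned posterior predictive check
#'
#' Observations are grouped by occasion and nearest protocol sampling time
#' (during infusion: 1, 4, 8, 12, 16, 20, 24 h; after cessation: 0, 5, 10,
#' 20 min and 1, 2, 4, 6 h past the infusion end). In each bin the observed
#' 10th/50th/90th percentiles are compared with 95% confidence intervals of
#' the same percentiles across posterior predictive replicates simulated
#' from the subjects' own posteriors ([simulate.dex_fit()]). An observed
#' percentile outside its interval flags local misfit.
#'
#' @param fit a [dex_fit()] result
#' @param n_rep number of posterior predictive replicates
#' @param seed integer seed for the replicate draws (local to this call)
#' @param min_bin_n bins with fewer observations are dropped with a warning
#' @return data frame of class `dex_ppc`: one row per bin and percentile
#'   with observed value, replicate 95% interval and an `outside` flag
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1,
                                       min_bin_n = 3) {
  bins <- .assign_bins(fit$prep)
  obs <- exp(fit$prep$obs_log_all)
  key <- paste0("occ", bins$occasion, "@", signif(bins$nominal, 4), "h")
  keep_keys <- names(which(table(key) >= min_bin_n))
  if (length(keep_keys) < length(unique(key)))
    warning("dropping ", length(unique(key)) - length(keep_keys),
            " bin(s) with fewer than ", min_bin_n, " observations")
  probs <- c(0.1, 0.5, 0.9)
  obs_pct <- t(vapply(keep_keys, function(k)
    quantile(obs[key == k], probs), numeric(3)))

  reps <- simulate(fit, nsim = n_rep, seed = seed)
  rep_pct <- array(NA_real_, c(n_rep, length(keep_keys), 3))
  for (r in seq_len(n_rep)) {
    cr <- reps[[r]]$conc # same row order as the prepared observations
    rep_pct[r, , ] <- t(vapply(keep_keys, function(k)
      quantile(cr[key == k], probs), numeric(3)))
  }
  rows <- lapply(seq_along(keep_keys), function(b) {
    k <- keep_keys[b]
    occ <- bins$occasion[key == k][1]
    nom <- bins$nominal[key == k][1]
    data.frame(bin = k, occasion = occ, nominal_time = nom,
               n_obs = sum(key == k),
               percentile = paste0("p", probs * 100),
               observed = obs_pct[b, ],
               pred_lo = apply(rep_pct[, b, , drop = FALSE], 3,
                               quantile, 0.025),
               pred_med = apply(rep_pct[, b, , drop = FALSE], 3, median),
               pred_hi = apply(rep_pct[, b, , drop = FALSE], 3,
                               quantile, 0.975))
  })
  out <- do.call(rbind, rows)
  out$outside <- out$observed < out$pred_lo | out$observed > out$pred_hi
  out <- out[order(out$occasion, out$nominal_time, out$percentile), ]
  rownames(out) <- NULL
  class(out) <- c("dex_ppc", "data.frame")
  out
}

#' @export
plot.dex_ppc <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (occ in 1:2) {
    d <- x[x$occasion == occ, ]
    if (!nrow(d)) next
    graphics::plot(NA, xlim = range(d$nominal_time), ylim = range(
      c(d$pred_lo, d$pred_hi, d$observed)), log = "y",
      xlab = if (occ == 1) "time since start (h)" else
        "time since cessation (h)",
      ylab = "concentration (ng/mL)",
      main = paste("occasion", occ), ...)
    for (p in unique(d$percentile)) {
      dp <- d[d$percentile == p, ]
      graphics::polygon(c(dp$nominal_time, rev(dp$nominal_time)),
                        c(dp$pred_lo, rev(dp$pred_hi)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(dp$nominal_time, dp$observed, type = "b", pch = 19)
    }
  }
  invisible(x)
}

#' Random-effect vs covariate screen
#'
#' Plots-ready association summaries between each subject's posterior-mean
#' random effects (`eta` for `CL`, `Q`, `V1`, `V2`) and the available
#' covariates: Spearman rank correlation for continuous covariates (age,
#' weight, total dose, infusion duration, PRISM) and the standardised group
#' difference for sex. Associations with `|statistic| >= threshold` are
#' flagged for inspection; the screen is graphical/tabular, not a formal
#' test. A constant covariate yields an undefined association, reported as
#' `NA`.
#'
#' @param fit a [dex_fit()] result
#' @param threshold flag cutoff on the absolute statistic (default 0.4)
#' @return data frame of class `dex_screen` with one row per
#'   (eta, covariate) pair, plus the per-subject table in
#'   `attr(, "subjects")`
#' @export
eta_covariate_screen <- function(fit, threshold = 0.4) {
  d <- do.call(rbind, fit$draws)
  prep <- fit$prep
  eta_mean <- sapply(.PK_PARS, function(p)
    colMeans(d[, paste0("eta_", p, "[", seq_len(prep$n), "]"),
               drop = FALSE]))
  cov_tab <- data.frame(
    age = vapply(prep$subs, `[[`, 0, "age"),
    weight = vapply(prep$subs, `[[`, 0, "bw"),
    dose = vapply(prep$subs, `[[`, 0, "total_dose"),
    duration = vapply(prep$subs, `[[`, 0, "duration"),
    prism = vapply(prep$subs, `[[`, 0, "prism"))
  sex <- vapply(prep$subs, `[[`, "", "sex")
  rows <- list()
  for (p in .PK_PARS) {
    e <- eta_mean[, p]
    for (cv in names(cov_tab)) {
      x <- cov_tab[[cv]]
      stat <- if (length(unique(x[!is.na(x)])) < 2) NA_real_ else
        suppressWarnings(cor(e, x, method = "spearman",
                             use = "complete.obs"))
      rows[[length(rows) + 1]] <- data.frame(
        eta = p, covariate = cv, type = "spearman", statistic = stat)
    }
    stat <- if (length(unique(sex)) < 2) NA_real_ else {
      dm <- mean(e[sex == "M"]) - mean(e[sex == "F"])
      s <- sd(e)
      if (s == 0) NA_real_ else dm / s
    }
    rows[[length(rows) + 1]] <- data.frame(
      eta = p, covariate = "sex", type = "std_mean_diff", statistic = stat)
  }
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$statistic) & abs(out$statistic) >= threshold
  attr(out, "threshold") <- threshold
  attr(out, "subjects") <- cbind(data.frame(
    id = vapply(prep$subs, function(s) as.character(s$id), ""),
    sex = sex), cov_tab, eta_mean)
  class(out) <- c("dex_screen", "data.frame")
  out
}
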