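#' Cohort design configuration
#'
#' Defaults reproduce the study design: 38 critically ill children aged
#' 1.4-188.6 months (median ~70), weighing 4.7-60 kg, 23:15 male:female,
#' PRISM scores 0-11 (median ~0.5), titrated infusions lasting 45-229.2 h,
#' and the two-occasion sampling schedule of [sampling_times()].
#'
#' @param n_subjects cohort size
#' @param age_range months, `(min, max)`
#' @param age_median months; the age distribution is piecewise log-uniform
#'   below and above this anchor so the cohort median matches the study
#' @param weight_range kg, `(min, max)` (clamp on the growth-curve draw)
#' @param p_male probability of male sex
#' @param prism_max maximum PRISM score
#' @param duration_range infusion duration range (h), sampled log-uniformly
#' @param jitter_sd lognormal SD of sampling-time jitter (0 = nominal grid)
#' @param seed integer seed used by [generate_dataset()] and
#'   [sample_demographics()]
#' @return a `dex_cohort_config` list
#' @export
cohort_config <- function(n_subjects = 38, age_range = c(1.4, 188.6),
                          age_median = 70, weight_range = c(4.7, 60),
                          p_male = 23 / 38, prism_max = 11,
                          duration_range = c(45, 229.2),
                          jitter_sd = 0.05, seed = 1) {
  stopifnot(n_subjects >= 1, age_range[1] > 0, diff(age_range) > 0,
            weight_range[1] > 0, diff(weight_range) > 0,
            duration_range[1] > 0, diff(duration_range) > 0,
            age_median > age_range[1], age_median < age_range[2])
  structure(as.list(environment()), class = "dex_cohort_config")
}

#' Titration policy
#'
#' The infusion starts at 0.8 ug/kg/h and is stepped by 0.2 ug/kg/h at
#' review times according to a latent two-state sedation-adequacy process:
#' an under-sedated review steps the rate up (capped at 1.4), an
#' over-sedated/weaning review steps it down (floored at `min_rate`).
#' The clinical sedation scoring itself is abstracted away; only the
#' resulting piecewise-constant dose trajectory matters for the kinetics.
#'
#' @param start_rate initial weight-normalised rate (ug/kg/h)
#' @param step rate increment/decrement (ug/kg/h)
#' @param max_rate cap (ug/kg/h)
#' @param min_rate floor while the infusion runs (ug/kg/h)
#' @param review_interval h between titration reviews
#' @param p_up,p_down per-review probabilities of stepping up / down
#' @return a `dex_titration_policy` list
#' @export
titration_policy <- function(start_rate = 0.8, step = 0.2, max_rate = 1.4,
                             min_rate = 0.2, review_interval = 12,
                             p_up = 0.15, p_down = 0.15) {
  stopifnot(start_rate <= max_rate, step > 0, min_rate >= 0,
            review_interval > 0, p_up >= 0, p_down >= 0, p_up + p_down <= 1)
  structure(as.list(environment()), class = "dex_titration_policy")
}

#' Generating (true) parameters for synthetic cohorts
#'
#' Defaults are the posterior means of the final study model, so synthetic
#' cohorts are statistically exchangeable with the study data: typical
#' values at 70 kg, occasion-2 fractions, between-subject %CVs, and the
#' robust residual model. All values can be overridden.
#'
#' @param theta named typical values `CL`, `Q` (L/h), `V1`, `V2` (L)
#' @param te50 maturation half-age (weeks)
#' @param hill maturation Hill coefficient
#' @param fractions named occasion-2 multipliers
#' @param iiv_cv named between-subject %CVs
#' @param sigma_C residual t scale (log-concentration units)
#' @param nu residual t degrees of freedom (> 1; small = heavy tails)
#' @param outlier_fraction probability an observation gets a gross
#'   multiplicative shock (5-10x up or down), in [0, 0.1]
#' @return a `dex_true_parameters` list
#' @export
true_parameters <- function(theta = c(CL = 41.6, Q = 56.8, V1 = 52.0,
                                      V2 = 70.4),
                            te50 = 42.5, hill = 2.45,
                            fractions = c(CL = 1.31, Q = 1.02, V1 = 1.50,
                                          V2 = 0.86),
                            iiv_cv = c(CL = 56, Q = 83, V1 = 152, V2 = 68),
                            sigma_C = 0.2, nu = 5, outlier_fraction = 0.03) {
  stopifnot(all(theta > 0), te50 > 0, hill > 0, all(fractions > 0),
            all(iiv_cv > 0), sigma_C >= 0, nu > 1,
            outlier_fraction >= 0, outlier_fraction <= 0.1)
  structure(as.list(environment()), class = "dex_true_parameters")
}

#' Sample cohort demographics
#'
#' Ages are piecewise log-uniform around the study median (half the cohort
#' below, half above, log-uniform within each side), weights follow a
#' smooth paediatric growth approximation of age (`(age + 9)/2` kg in
#' infancy, linear in age above one year) with lognormal spread, clamped to
#' the configured range; sex is drawn at the configured ratio; PRISM scores
#' are geometric-tailed with most children at 0-1; postmenstrual age
#' assumes term gestation (40 weeks) plus postnatal age.
#'
#' @param config a [cohort_config()]; set `config$seed` to `NULL` to draw
#'   from the current RNG state
#' @return data frame with `id`, `age` (months), `pma` (weeks), `bw` (kg),
#'   `sex`, `prism`
#' @export
sample_demographics <- function(config = cohort_config()) {
  if (!is.null(config$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
  }
  n <- config$n_subjects
  lower <- runif(n) < 0.5
  age <- ifelse(lower,
                exp(runif(n, log(config$age_range[1]),
                          log(config$age_median))),
                exp(runif(n, log(config$age_median),
                          log(config$age_range[2]))))
  bw <- pmin(pmax(.growth_curve(age) * rlnorm(n, 0, 0.15),
                  config$weight_range[1]), config$weight_range[2])
  sex <- ifelse(runif(n) < config$p_male, "M", "F")
  prism <- pmin(rgeom(n, 0.5), config$prism_max)
  data.frame(id = seq_len(n), age = age, pma = 40 + age * (365.25 / 12) / 7,
             bw = bw, sex = sex, prism = prism)
}

# deterministic paediatric age-weight approximation (kg from months):
# (age+9)/2 in the first year, then linear 2 kg/year from 10.5 kg
.growth_curve <- function(age_months)
  ifelse(age_months <= 12, (age_months + 9) / 2,
         10.5 + 2 * (age_months - 12) / 12)

#' Simulate a titrated infusion schedule
#'
#' @param bw body weight (kg)
#' @param policy a [titration_policy()]
#' @param duration total infusion duration (h); the rate drops to zero at
#'   `duration`
#' @param seed optional integer seed (local to this call)
#' @return a [dose_events()] data frame of piecewise-constant infusion
#'   segments (rates in ug/h)
#' @export
simulate_dosing <- function(bw, policy = titration_policy(), duration,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  stopifnot(bw > 0, duration > 0)
  reviews <- seq(0, duration, by = policy$review_interval)
  rate_kg <- policy$start_rate
  starts <- 0; rates <- rate_kg
  for (tr in reviews[-1]) {
    if (tr >= duration) break
    u <- runif(1)
    new_rate <- if (u < policy$p_up)
      min(rate_kg + policy$step, policy$max_rate)
    else if (u < policy$p_up + policy$p_down)
      max(rate_kg - policy$step, policy$min_rate)
    else rate_kg
    if (new_rate != rate_kg) {
      rate_kg <- new_rate
      starts <- c(starts, tr); rates <- c(rates, rate_kg)
    }
  }
  ends <- c(starts[-1], duration)
  dose_events(start = starts, rate = rates * bw, duration = ends - starts)
}

#' Protocol sampling schedule
#'
#' Occasion 1 (during infusion): a pre-dose sample at 0 h and samples at
#' 1, 4, 8, 12, 16, 20, 24 h after the start. Occasion 2 (after cessation):
#' at the infusion end and 5, 10, 20 min and 1, 2, 4, 6 h later. Optional
#' multiplicative lognormal jitter emulates deviation from nominal times
#' (the pre-dose and cessation anchors stay exact); occasion-1 samples are
#' truncated, with a warning, for infusions shorter than 24 h.
#'
#' @param infusion_end cessation time (h)
#' @param jitter_sd lognormal SD of the time jitter (0 = exact nominal grid)
#' @param seed optional integer seed (local to this call)
#' @return data frame with `time` (h) and `occasion`; the 0 h row is the
#'   pre-dose design sample
#' @export
sampling_times <- function(infusion_end, jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  stopifnot(infusion_end > 0)
  occ1 <- .NOMINAL_OCC1
  if (infusion_end <= 24) {
    warning("infusion shorter than 24 h: occasion-1 samples truncated")
    occ1 <- occ1[occ1 < infusion_end]
  }
  occ2_off <- .NOMINAL_OCC2
  if (jitter_sd > 0) {
    occ1 <- sort(pmin(occ1 * rlnorm(length(occ1), 0, jitter_sd),
                      infusion_end * 0.999))
    pos <- occ2_off > 0
    occ2_off[pos] <- sort(occ2_off[pos] * rlnorm(sum(pos), 0, jitter_sd))
  }
  data.frame(time = c(0, occ1, infusion_end + occ2_off),
             occasion = c(rep(1L, 1 + length(occ1)),
                          rep(2L, length(occ2_off))))
}

#' Generate a synthetic study cohort
#'
#' Draws demographics, titrated dosing and the two-occasion sampling
#' schedule, samples between-subject random effects
#' `eta ~ MVN(0, Omega_true)`, builds occasion-specific individual
#' parameters (allometry, maturation, fractions), computes the
#' two-compartment concentrations, and adds Student-t noise on the log
#' scale, with occasional gross outliers (5-10x multiplicative shocks).
#' The pre-dose sample has concentration exactly zero and is kept as a
#' design row only. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()]
#' @param policy a [titration_policy()]
#' @param truth a [true_parameters()]
#' @return a [dex_data()] object
#' @export
generate_dataset <- function(config = cohort_config(),
                             policy = titration_policy(),
                             truth = true_parameters()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config; cfg_noseed$seed <- NULL
  demo <- sample_demographics(cfg_noseed)
  n <- nrow(demo)
  omega <- diag(iiv_variance_from_cv(truth$iiv_cv), 4)
  # the generating Omega is diagonal, so independent per-column scaling
  # (also well-defined in the noiseless iiv -> 0 limit)
  etas <- matrix(rnorm(4 * n), n, 4) %*% diag(sqrt(diag(omega)), 4)
  colnames(etas) <- .PK_PARS
  pop <- list(theta = truth$theta, te50 = truth$te50, hill = truth$hill,
              fractions = truth$fractions)
  subs <- lapply(seq_len(n), function(j) {
    dur <- exp(runif(1, log(config$duration_range[1]),
                     log(config$duration_range[2])))
    doses <- simulate_dosing(demo$bw[j], policy, dur)
    st <- sampling_times(dur, jitter_sd = config$jitter_sd)
    cov_j <- list(bw = demo$bw[j], pma = demo$pma[j])
    p1 <- individual_parameters(pop, cov_j, etas[j, ], occasion = 1)
    p2 <- individual_parameters(pop, cov_j, etas[j, ], occasion = 2)
    grid <- .dose_grid(doses)
    obs <- st[st$time > 0, ]
    pred <- .cpp_pk_profile(grid$seg_t, grid$seg_rate, grid$seg_bolus,
                            p1, p2, grid$cessation, obs$time)
    logc <- log(pred)
    if (truth$sigma_C > 0)
      logc <- logc + truth$sigma_C * rt(nrow(obs), truth$nu)
    if (truth$outlier_fraction > 0) {
      hit <- runif(nrow(obs)) < truth$outlier_fraction
      if (any(hit)) {
        shock <- runif(sum(hit), 5, 10)^(sign(runif(sum(hit)) - 0.5))
        logc[hit] <- log(pred[hit]) + log(shock)
      }
    }
    .subject(id = demo$id[j], bw = demo$bw[j], age = demo$age[j],
             pma = demo$pma[j], sex = demo$sex[j], prism = demo$prism[j],
             doses = doses,
             obs = data.frame(time = obs$time, conc = exp(logc),
                              occasion = obs$occasion),
             predose = 0)
  })
  new_dex_data(subs)
}
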