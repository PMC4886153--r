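# Shared fixtures. Expensive fits are memoised so several test files can
# reuse them without refitting.

.fixtures <- new.env(parent = emptyenv())

# small cohort for fast sampler tests
small_cohort <- function(n = 8, seed = 3, ...)
  generate_dataset(cohort_config(n_subjects = n, seed = seed, ...))

# study-scale recovery fixture: 38 subjects generated at the final-model
# posterior means, fitted with the literature priors at the reduced
# protocol (3 x 2000, burn-in 1000, thin 2)
recovery_data <- function() {
  if (is.null(.fixtures$rec_data))
    .fixtures$rec_data <- generate_dataset(cohort_config(seed = 42))
  .fixtures$rec_data
}

recovery_fit <- function() {
  if (is.null(.fixtures$rec_fit))
    .fixtures$rec_fit <- suppressWarnings(dex_fit(
      recovery_data(), build_priors(),
      dex_control(n_chains = 3, n_iter = 2000, burn_in = 1000, thin = 2,
                  seed = 11)))
  .fixtures$rec_fit
}

# same data fitted without occasion fractions (for the DIC comparison)
nofraction_fit <- function() {
  if (is.null(.fixtures$nof_fit))
    .fixtures$nof_fit <- suppressWarnings(dex_fit(
      recovery_data(), build_priors(),
      dex_control(n_chains = 3, n_iter = 2000, burn_in = 1000, thin = 2,
                  seed = 11, include_fractions = FALSE)))
  .fixtures$nof_fit
}

# generating values behind recovery_data() (true_parameters() defaults)
GEN_THETA <- c(CL = 41.6, Q = 56.8, V1 = 52.0, V2 = 70.4,
               TE50 = 42.5, Hill = 2.45)
GEN_F <- c(CL = 1.31, Q = 1.02, V1 = 1.50, V2 = 0.86)

# numerical ODE oracle for the two-compartment infusion model (deSolve),
# independent of the analytic kernel; params may switch at `switch_time`
ode_profile <- function(params, doses, times, params2 = params,
                        switch_time = Inf) {
  # piecewise integration with a restart at every discontinuity (dose
  # boundaries, boluses, the occasion switch, observation times)
  inf <- doses[doses$rate > 0, , drop = FALSE]
  bol <- doses[doses$rate == 0, , drop = FALSE]
  brk <- sort(unique(c(0, inf$start, inf$start + inf$duration, bol$start,
                       if (is.finite(switch_time)) switch_time, times)))
  state <- c(A1 = 0, A2 = 0)
  out <- numeric(length(times))
  for (k in seq_along(brk)) {
    t0 <- brk[k]
    if (nrow(bol))
      state[1] <- state[1] + sum(bol$amount[abs(bol$start - t0) < 1e-12])
    pp <- if (t0 >= switch_time) params2 else params
    out[abs(times - t0) < 1e-12] <- state[["A1"]] / pp[["V1"]]
    if (k == length(brk)) break
    t1 <- brk[k + 1]
    rate <- sum(inf$rate[inf$start <= t0 + 1e-12 &
                           inf$start + inf$duration > t0 + 1e-12])
    deriv <- function(t, y, parms) with(as.list(pp), list(c(
      rate - (CL + Q) / V1 * y[1] + Q / V2 * y[2],
      Q / V1 * y[1] - Q / V2 * y[2])))
    sol <- deSolve::lsoda(state, c(t0, t1), deriv, NULL,
                          rtol = 1e-11, atol = 1e-13)
    state <- sol[nrow(sol), c("A1", "A2")]
  }
  out
}

# build a minimal dex_data object directly from components
manual_data <- function(doses, obs, bw = 70, pma = 2000, id = 1,
                        age = 120, sex = "M", prism = 0) {
  s <- dexpk:::.subject(id = id, bw = bw, age = age, pma = pma, sex = sex,
                        prism = prism, doses = doses, obs = obs)
  dexpk:::new_dex_data(list(s))
}
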