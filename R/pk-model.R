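#' Dose events
#'
#' Construct a table of dose events for the two-compartment kernel. An
#' infusion has `rate > 0` and `duration > 0` (its `amount` is
#' `rate * duration`); a bolus has `rate = 0`, `duration = 0` and
#' `amount > 0`. Units are micrograms and hours, so concentrations come out
#' in ug/L, numerically equal to ng/mL.
#'
#' @param start start time of the event (h, >= 0)
#' @param rate infusion rate (ug/h); 0 for a bolus
#' @param duration infusion duration (h); 0 for a bolus
#' @param amount dose amount (ug); defaults to `rate * duration` for
#'   infusions and must be given for boluses
#' @return a `data.frame` with columns `start`, `rate`, `duration`, `amount`
#' @examples
#' dose_events(start = 0, rate = 14.8, duration = 97.3)
#' @export
dose_events <- function(start, rate = 0, duration = 0, amount = NULL) {
  if (length(start) == 0)
    return(data.frame(start = numeric(0), rate = numeric(0),
                      duration = numeric(0), amount = numeric(0)))
  n <- max(length(start), length(rate), length(duration))
  start <- rep_len(start, n); rate <- rep_len(rate, n)
  duration <- rep_len(duration, n)
  if (is.null(amount)) amount <- rate * duration
  amount <- rep_len(amount, n)
  d <- data.frame(start = as.numeric(start), rate = as.numeric(rate),
                  duration = as.numeric(duration), amount = as.numeric(amount))
  .check_doses(d)
  d
}

.check_doses <- function(d) {
  if (nrow(d) == 0) return(invisible(d))
  with(d, {
    if (any(start < 0)) .dex_stop("dose start times must be non-negative")
    if (any(duration < 0) || any(rate < 0) || any(amount < 0))
      .dex_stop("dose rate, duration and amount must be non-negative")
    inf <- rate > 0 | duration > 0
    if (any(inf & (rate <= 0 | duration <= 0)))
      .dex_stop("an infusion needs both rate > 0 and duration > 0")
    if (any(!inf & amount <= 0))
      .dex_stop("a bolus needs amount > 0")
    if (any(abs(amount[inf] - rate[inf] * duration[inf]) >
            1e-8 * pmax(1, amount[inf])))
      .dex_stop("infusion amount must equal rate * duration")
  })
  invisible(d)
}

.check_params <- function(p) {
  p <- unlist(p)[.PK_PARS]
  if (anyNA(p) || any(p <= 0))
    .dex_stop("PK parameters CL, Q, V1, V2 must all be strictly positive")
  as.numeric(p)
}

# Collapse dose events into the piecewise-constant grid the C++ kernel walks:
# segment start times, total rate per segment (overlapping infusions add) and
# bolus amounts at segment starts.
.dose_grid <- function(doses) {
  if (nrow(doses) == 0)
    return(list(seg_t = numeric(0), seg_rate = numeric(0),
                seg_bolus = numeric(0), cessation = Inf))
  inf <- doses$rate > 0
  ev_t <- c(doses$start[inf], doses$start[inf] + doses$duration[inf],
            doses$start[!inf])
  dr   <- c(doses$rate[inf], -doses$rate[inf], rep(0, sum(!inf)))
  bol  <- c(rep(0, 2 * sum(inf)), doses$amount[!inf])
  o <- order(ev_t)
  ev_t <- ev_t[o]; dr <- dr[o]; bol <- bol[o]
  seg_t <- unique(ev_t)
  g <- match(ev_t, seg_t)
  seg_rate  <- cumsum(vapply(split(dr, g), sum, 0))
  seg_bolus <- vapply(split(bol, g), sum, 0)
  # guard against float dust in the rate after the last infusion ends
  seg_rate[abs(seg_rate) < 1e-9] <- 0
  cess <- if (any(inf)) max(doses$start[inf] + doses$duration[inf]) else Inf
  list(seg_t = seg_t, seg_rate = unname(seg_rate),
       seg_bolus = unname(seg_bolus), cessation = cess)
}

.profile_grid <- function(grid, p1, p2 = p1, switch_time = Inf, times) {
  .cpp_pk_profile(grid$seg_t, grid$seg_rate, grid$seg_bolus,
                  p1, p2, switch_time, times)
}

#' Central-compartment concentration profile
#'
#' Closed-form solution of the two-compartment infusion model: the linear
#' system is propagated exactly through each piecewise-constant dosing
#' segment via the matrix exponential, which is equivalent to superposing
#' biexponential responses of all dose events. Concentrations are zero
#' before the first dose, and linear in dose.
#'
#' @param params named vector or list with `CL`, `Q` (L/h) and `V1`, `V2`
#'   (L), all strictly positive
#' @param doses a data frame from [dose_events()]; overlapping infusions are
#'   additive
#' @param times evaluation times (h, non-negative); an observation falling
#'   exactly on an event boundary is evaluated just after the event
#' @return central concentrations (ug/L = ng/mL) at `times`, in input order
#' @examples
#' p <- c(CL = 41.6, Q = 56.8, V1 = 52.0, V2 = 70.4)
#' concentration_profile(p, dose_events(0, rate = 56, duration = 24),
#'                       times = c(1, 24, 24.5))
#' @export
concentration_profile <- function(params, doses, times) {
  p <- .check_params(params)
  .check_doses(doses)
  if (any(times < 0)) .dex_stop("evaluation times must be non-negative")
  o <- order(times)
  out <- numeric(length(times))
  out[o] <- .profile_grid(.dose_grid(doses), p, times = times[o])
  out
}

#' Allometric body-weight multiplier
#'
#' Power-law scaling `(bw / 70)^K` relative to a 70 kg adult; `K = 0.75`
#' for clearance terms and `K = 1` for distribution volumes.
#'
#' @param bw body weight (kg, > 0); vectorised
#' @param K allometric exponent
#' @return unitless multiplier
#' @export
allometric_multiplier <- function(bw, K) {
  if (any(bw <= 0)) .dex_stop("body weight must be strictly positive")
  (bw / .REF_BW)^K
}

#' Clearance maturation fraction
#'
#' Hill function of postmenstrual age,
#' `pma^hill / (pma^hill + te50^hill)`: the fraction of adult clearance
#' attained at `pma` weeks, 0.5 at `pma = te50`, approaching 1 in adults.
#'
#' @param pma postmenstrual age (weeks, > 0); vectorised
#' @param te50 age at half of adult clearance (weeks, > 0)
#' @param hill Hill coefficient (> 0) setting the steepness of maturation
#' @return maturation fraction in (0, 1)
#' @export
maturation_fraction <- function(pma, te50, hill) {
  if (any(pma <= 0) || any(te50 <= 0) || any(hill <= 0))
    .dex_stop("pma, te50 and hill must be strictly positive")
  # computed on the log scale to stay finite for extreme hill exponents
  1 / (1 + exp(hill * (log(te50) - log(pma))))
}

#' Individual pharmacokinetic parameters
#'
#' Maps population parameters, covariates and random effects to one
#' subject's `CL`, `Q`, `V1`, `V2` on one occasion:
#' `ln P_i = ln theta_P + ln f_P [occasion 2] + K ln(BW/70) + eta_P`,
#' with the maturation fraction of [maturation_fraction()] multiplying
#' clearance only. Occasion 1 covers the infusion; occasion 2 starts at
#' infusion cessation, when every parameter shifts by its fraction `f_P`.
#'
#' @param pop list with typical values `theta` (named `CL`, `Q`, `V1`, `V2`
#'   at 70 kg), `te50`, `hill`, and `fractions` (named occasion-2 multipliers,
#'   all 1 for no shift)
#' @param covariates list or one-row data frame with `bw` (kg) and
#'   `pma` (weeks)
#' @param eta named log-scale random effects for `CL`, `Q`, `V1`, `V2`
#'   (default all zero)
#' @param occasion 1 (during infusion) or 2 (after cessation)
#' @return named vector of individual `CL`, `Q` (L/h), `V1`, `V2` (L)
#' @export
individual_parameters <- function(pop, covariates,
                                  eta = c(CL = 0, Q = 0, V1 = 0, V2 = 0),
                                  occasion = 1) {
  if (!occasion %in% c(1, 2)) .dex_stop("occasion must be 1 or 2")
  th <- unlist(pop$theta)[.PK_PARS]
  if (anyNA(th) || any(th <= 0)) .dex_stop("typical values must be positive")
  f <- if (occasion == 2) unlist(pop$fractions)[.PK_PARS] else
    c(CL = 1, Q = 1, V1 = 1, V2 = 1)
  eta <- unlist(eta)[.PK_PARS]
  K <- c(CL = 0.75, Q = 0.75, V1 = 1, V2 = 1) # fixed theory-based exponents
  lp <- log(th) + log(f) + K * log(covariates$bw / .REF_BW) + eta
  lp["CL"] <- lp["CL"] +
    log(maturation_fraction(covariates$pma, pop$te50, pop$hill))
  setNames(exp(lp), .PK_PARS)
}
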