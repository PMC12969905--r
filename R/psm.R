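#' Economic settings for the partitioned survival model
#'
#' Defaults encode the base-case evaluation frame: 21-day cycles over a
#' 20-year horizon, 3% annual discounting of both costs and effects, and
#' a willingness-to-pay threshold of NT$2,917,650 per QALY (three times
#' 2022 GDP per capita in Taiwan).
#'
#' @param cycle_days Cycle length in days.
#' @param horizon_years Time horizon in years.
#' @param disc_effects,disc_costs Annual discount rates.
#' @param wtp Willingness-to-pay threshold, NT$ per unit of effect.
#' @return An `econ_params` list.
#' @export
econ_params <- function(cycle_days = 21, horizon_years = 20,
                        disc_effects = 0.03, disc_costs = 0.03,
                        wtp = 2917650) {
  stopifnot(cycle_days > 0, horizon_years * 365.25 >= cycle_days,
            disc_effects >= 0, disc_costs >= 0, wtp > 0)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 disc_effects = disc_effects, disc_costs = disc_costs,
                 wtp = wtp), class = "econ_params")
}

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Adverse event profile
#'
#' One row per grade >= 3 adverse event: the per-patient risk, the
#' one-time management cost (NT$) and the utility decrement. Events with
#' no published cost or disutility carry 0.
#'
#' @param name,risk,cost,disutility Vectors of equal length.
#' @return An `ae_profile` data frame.
#' @export
ae_profile <- function(name = character(0), risk = numeric(0),
                       cost = numeric(0), disutility = numeric(0)) {
  stopifnot(all(risk >= 0 & risk <= 1), all(cost >= 0),
            all(disutility >= 0 & disutility <= 1))
  structure(data.frame(name = name, risk = risk, cost = cost,
                       disutility = disutility),
            class = c("ae_profile", "data.frame"))
}

#' Treatment strategy specification
#'
#' Bundles everything the cohort trace needs for one arm: OS and PFS
#' curves (parametric models or plain survival functions of time in
#' months), per-cycle medication cost components with optional cycle
#' caps, per-cycle non-medication cost while progression-free, per-cycle
#' supportive-care cost while progressed, state utilities, and the
#' adverse-event profile (applied once, in the first cycle of the
#' progression-free state).
#'
#' @param name Strategy label.
#' @param os,pfs Survival curves: `parsurv` objects or functions
#'   `S(t months)`.
#' @param med Data frame of medication components: `label`,
#'   `cost_per_cycle` (NT$), `max_cycles` (`Inf` = unbounded).
#' @param pf_nonmed Per-cycle non-medication cost in the PF state (NT$).
#' @param pd_cost Per-cycle supportive-care cost in the PD state (NT$).
#' @param utility_pf,utility_pd State utilities in \[0, 1\].
#' @param ae An [ae_profile()].
#' @return A `strategy_spec` list.
#' @export
strategy_spec <- function(name, os, pfs, med, pf_nonmed, pd_cost,
                          utility_pf, utility_pd, ae = ae_profile()) {
  stopifnot(utility_pf >= 0, utility_pf <= 1, utility_pd >= 0,
            utility_pd <= 1, pf_nonmed >= 0, pd_cost >= 0,
            all(c("label", "cost_per_cycle", "max_cycles") %in% names(med)),
            all(med$cost_per_cycle >= 0), all(med$max_cycles > 0))
  structure(list(name = name, os = as_surv_fun(os), pfs = as_surv_fun(pfs),
                 med = as.data.frame(med), pf_nonmed = pf_nonmed,
                 pd_cost = pd_cost, utility_pf = utility_pf,
                 utility_pd = utility_pd, ae = ae),
            class = "strategy_spec")
}

as_surv_fun <- function(x) {
  if (is.function(x)) return(x)
  x <- as_parsurv(x)
  function(t) surv_prob(x, t)
}

#' Health-state membership of the partitioned survival model
#'
#' PF = min(PFS(t), OS(t)); PD = OS(t) - PF; dead = 1 - OS(t). Crossing
#' curves (PFS above OS) are clamped so that PD >= 0; the number of
#' clamped time points is reported in the `"n_clamped"` attribute.
#'
#' @param os,pfs Survival functions or `parsurv` models.
#' @param t Times in months (vectorized).
#' @return Data frame with columns `pf`, `pd`, `dead`, rows summing to 1.
#' @export
state_membership <- function(os, pfs, t) {
  if (any(t < 0)) stop("t must be >= 0")
  os <- as_surv_fun(os)
  pfs <- as_surv_fun(pfs)
  s_os <- pmin(pmax(os(t), 0), 1)
  s_pfs <- pmin(pmax(pfs(t), 0), 1)
  pf <- pmin(s_pfs, s_os)
  out <- data.frame(pf = pf, pd = s_os - pf, dead = 1 - s_os)
  attr(out, "n_clamped") <- sum(s_pfs > s_os)
  out
}

#' Run the discounted cohort trace for one strategy
#'
#' Cycles k = 1..K with K = floor(horizon / cycle length); state
#' membership is evaluated at the end of each cycle (or mid-cycle with
#' `half_cycle = TRUE`). Per cycle, each state's life-year increment is
#' membership x cycle length in years x discount factor; QALY increments
#' additionally weight by the state utility; costs accrue as medication
#' components x PF membership (each component truncated at its cycle
#' cap), PF non-medication cost x PF, and supportive care x PD, each
#' discounted. The expected adverse-event cost (sum risk x cost) and QALY
#' decrement (sum risk x disutility, for one cycle's duration) are
#' applied once in cycle 1 and attributed to the PF state. Discounting is
#' annual-compound at the cycle's time in years: (1+r)^(-t/365.25 days).
#'
#' @param strategy A [strategy_spec()].
#' @param econ An [econ_params()].
#' @param half_cycle Evaluate membership at mid-cycle instead of
#'   end-of-cycle.
#' @return A `cohort_trace` data frame (one row per cycle, with
#'   membership and discounted per-state increments) carrying a `totals`
#'   attribute; see [summarize_trace()].
#' @export
run_trace <- function(strategy, econ = econ_params(), half_cycle = FALSE) {
  stopifnot(inherits(strategy, "strategy_spec"))
  K <- floor(econ$horizon_years * DAYS_PER_YEAR / econ$cycle_days)
  if (K < 1) stop("horizon shorter than one cycle")
  k <- seq_len(K)
  eval_k <- if (half_cycle) k - 0.5 else k
  t_days <- eval_k * econ$cycle_days
  t_months <- t_days / DAYS_PER_MONTH
  t_years <- t_days / DAYS_PER_YEAR
  cyc_years <- econ$cycle_days / DAYS_PER_YEAR
  disc_e <- (1 + econ$disc_effects)^(-t_years)
  disc_c <- (1 + econ$disc_costs)^(-t_years)

  m <- state_membership(strategy$os, strategy$pfs, t_months)

  ly_pf <- m$pf * cyc_years * disc_e
  ly_pd <- m$pd * cyc_years * disc_e
  qaly_pf <- ly_pf * strategy$utility_pf
  qaly_pd <- ly_pd * strategy$utility_pd

  cost_med <- numeric(K)
  for (i in seq_len(nrow(strategy$med))) {
    active <- k <= strategy$med$max_cycles[i]
    cost_med <- cost_med +
      strategy$med$cost_per_cycle[i] * m$pf * disc_c * active
  }
  cost_nonmed_pf <- strategy$pf_nonmed * m$pf * disc_c
  cost_pd <- strategy$pd_cost * m$pd * disc_c

  cost_ae <- numeric(K)
  qaly_ae_loss <- numeric(K)
  if (nrow(strategy$ae)) {
    cost_ae[1] <- sum(strategy$ae$risk * strategy$ae$cost) * disc_c[1]
    qaly_ae_loss[1] <- sum(strategy$ae$risk * strategy$ae$disutility) *
      cyc_years * disc_e[1]
  }

  trace <- data.frame(cycle = k, time_months = t_months,
                      time_years = t_years,
                      pf = m$pf, pd = m$pd, dead = m$dead,
                      ly_pf = ly_pf, ly_pd = ly_pd,
                      qaly_pf = qaly_pf, qaly_pd = qaly_pd,
                      cost_med = cost_med,
                      cost_nonmed_pf = cost_nonmed_pf,
                      cost_pd = cost_pd, cost_ae = cost_ae,
                      qaly_ae_loss = qaly_ae_loss)
  totals <- list(
    strategy = strategy$name,
    ly_pf = sum(ly_pf), ly_pd = sum(ly_pd), ly = sum(ly_pf) + sum(ly_pd),
    qaly_pf = sum(qaly_pf) - sum(qaly_ae_loss),
    qaly_pd = sum(qaly_pd),
    qaly = sum(qaly_pf) + sum(qaly_pd) - sum(qaly_ae_loss),
    cost_pf = sum(cost_med) + sum(cost_nonmed_pf) + sum(cost_ae),
    cost_pd = sum(cost_pd),
    cost = sum(cost_med) + sum(cost_nonmed_pf) + sum(cost_ae) +
      sum(cost_pd),
    n_clamped = attr(m, "n_clamped"))
  attr(trace, "totals") <- totals
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

#' Totals of a cohort trace
#'
#' @param trace A `cohort_trace` from [run_trace()].
#' @return One-row data frame of discounted totals: cost, life-years and
#'   QALYs, each split by PF and PD state (the one-time adverse-event
#'   cost and QALY decrement are attributed to the PF state).
#' @export
summarize_trace <- function(trace) {
  tot <- attr(trace, "totals")
  if (is.null(tot)) stop("not a cohort_trace: missing totals")
  data.frame(strategy = tot$strategy,
             cost = tot$cost, cost_pf = tot$cost_pf, cost_pd = tot$cost_pd,
             ly = tot$ly, ly_pf = tot$ly_pf, ly_pd = tot$ly_pd,
             qaly = tot$qaly, qaly_pf = tot$qaly_pf, qaly_pd = tot$qaly_pd)
}
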