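#' Define one uncertain model parameter
#'
#' A parameter specification carries the base value, the deterministic
#' sensitivity bounds, the probabilistic sampling distribution, and a
#' setter that writes a value into a model configuration. Supported PSA
#' families and their parameter pairs:
#'
#' * `normal(mean, sd)`
#' * `beta_ab(alpha, beta)` — direct shape pair
#' * `beta_counts(events, n_total)` — Beta(events, n_total - events)
#' * `uniform(lo, hi)`
#' * `gamma_meansd(mean, sd)` — shape (mean/sd)^2, scale sd^2/mean
#' * `fixed` — degenerate at the base value
#'
#' `psa_scale` multiplies each draw before it enters the model (used for
#' per-day drug prices sampled on the day scale but applied per cycle).
#' `support` is a closed-open validity interval; draws outside it are
#' redrawn.
#'
#' @param name Parameter label.
#' @param base Base-case value (model scale).
#' @param dsa_low,dsa_high Deterministic sensitivity bounds (model scale).
#' @param psa_family One of the families above.
#' @param psa_pars Numeric pair for the family.
#' @param set Function `(config, value) -> config`.
#' @param psa_scale Multiplier applied to raw draws.
#' @param support Length-2 validity interval for the scaled draw.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, base, dsa_low, dsa_high, psa_family,
                       psa_pars = c(NA_real_, NA_real_), set,
                       psa_scale = 1, support = c(-Inf, Inf)) {
  psa_family <- match.arg(psa_family,
                          c("normal", "beta_ab", "beta_counts", "uniform",
                            "gamma_meansd", "fixed"))
  if (!(dsa_low <= base && base <= dsa_high)) {
    stop("param '", name, "': need dsa_low <= base <= dsa_high")
  }
  if (psa_family != "fixed") {
    if (any(!is.finite(psa_pars))) {
      stop("param '", name, "': missing distribution parameters")
    }
    ok <- switch(psa_family,
      normal = psa_pars[2] > 0,
      beta_ab = all(psa_pars > 0),
      beta_counts = psa_pars[1] > 0 && psa_pars[2] > psa_pars[1],
      uniform = psa_pars[1] < psa_pars[2],
      gamma_meansd = all(psa_pars > 0))
    if (!ok) stop("param '", name, "': invalid ", psa_family,
                  " parameters")
  }
  structure(list(name = name, base = base, dsa_low = dsa_low,
                 dsa_high = dsa_high, psa_family = psa_family,
                 psa_pars = psa_pars, set = set, psa_scale = psa_scale,
                 support = support), class = "param_spec")
}

# --- setter factories ----------------------------------------------------

set_surv_param <- function(arm, curve, pname) {
  force(arm); force(curve); force(pname)
  function(cfg, v) {
    cfg$strategies[[arm]][[curve]]$params[[pname]] <- v
    cfg
  }
}

set_ae_field <- function(arms, ae_name, field) {
  force(arms); force(ae_name); force(field)
  function(cfg, v) {
    for (a in arms) {
      df <- as.data.frame(cfg$strategies[[a]]$ae)
      df[df$name == ae_name, field] <- v
      cfg$strategies[[a]]$ae <- df
    }
    cfg
  }
}

set_med_cost <- function(arm, label) {
  force(arm); force(label)
  function(cfg, v) {
    df <- as.data.frame(cfg$strategies[[arm]]$med)
    df[df$label == label, "cost_per_cycle"] <- v
    cfg$strategies[[arm]]$med <- df
    cfg
  }
}

set_strategy_field <- function(arms, field) {
  force(arms); force(field)
  function(cfg, v) {
    for (a in arms) cfg$strategies[[a]][[field]] <- v
    cfg
  }
}

# Beta shapes by method of moments from a mean and standard deviation.
beta_from_moments <- function(m, s) {
  v <- s^2
  c <- m * (1 - m) / v - 1
  if (c <= 0) stop("moments incompatible with a beta distribution")
  c(m * c, (1 - m) * c)
}

#' Uncertain-parameter set of the base-case model
#'
#' All 44 uncertain parameters of the shipped base case: the eight
#' survival-model parameters (normal, sd from the fit standard errors;
#' deterministic bounds are the 95% confidence limits), sixteen
#' arm-specific adverse-event risks (beta from event counts over trial
#' arm sizes 406 and 388), two state utilities and six adverse-event
#' disutilities (beta; the three disutilities published without shape
#' pairs get method-of-moments shapes treating the +/-25% deterministic
#' range as +/-2 sd), four medication costs (lenvatinib uniform on its
#' per-day price 1,452-2,420 scaled by 21 days/cycle; pembrolizumab
#' uniform 74,001-123,335 per cycle; doxorubicin and other chemotherapy
#' gamma by mean/sd), six adverse-event management costs and the two
#' non-medication state costs (gamma by mean/sd). Deterministic bounds
#' not tied to confidence intervals are +/-25% of base.
#'
#' @return List of [param_spec()] objects.
#' @export
base_case_params <- function() {
  both <- c("lp", "chemo")
  sp <- list()
  add <- function(...) sp[[length(sp) + 1]] <<- param_spec(...)

  # survival parameters: name, arm, curve, par, base, lo, hi, se
  sv <- list(
    list("lp_os_meanlog", "lp", "os", "meanlog", 2.911, 2.781, 3.042,
         0.067, c(-Inf, Inf)),
    list("lp_os_sdlog", "lp", "os", "sdlog", 1.245, 1.138, 1.262, 0.057,
         c(1e-6, Inf)),
    list("chemo_os_shape", "chemo", "os", "shape", 1.683, 1.538, 1.841,
         0.077, c(1e-6, Inf)),
    list("chemo_os_scale", "chemo", "os", "scale", 11.905, 10.760, 13.172,
         0.614, c(1e-6, Inf)),
    list("lp_pfs_meanlog", "lp", "pfs", "meanlog", 2.002, 1.883, 2.121,
         0.061, c(-Inf, Inf)),
    list("lp_pfs_sdlog", "lp", "pfs", "sdlog", 1.172, 1.089, 1.276, 0.048,
         c(1e-6, Inf)),
    list("chemo_pfs_shape", "chemo", "pfs", "shape", 1.885, 1.721, 2.065,
         0.088, c(1e-6, Inf)),
    list("chemo_pfs_scale", "chemo", "pfs", "scale", 3.956, 3.597, 4.351,
         0.192, c(1e-6, Inf)))
  for (x in sv) {
    add(name = x[[1]], base = x[[5]], dsa_low = x[[6]], dsa_high = x[[7]],
        psa_family = "normal", psa_pars = c(x[[5]], x[[8]]),
        set = set_surv_param(x[[2]], x[[3]], x[[4]]), support = x[[9]])
  }

  # adverse-event risks: event counts over arm denominators
  risks <- list(
    lp = list(hypertension = c(0.392, 0.294, 0.490, 159),
              diarrhea = c(0.081, 0.061, 0.101, 33),
              decreased_appetite = c(0.076, 0.057, 0.095, 31),
              weight_loss = c(0.108, 0.081, 0.135, 44),
              fatigue = c(0.054, 0.041, 0.068, 22),
              proteinuria = c(0.052, 0.039, 0.065, 21),
              anemia = c(0.069, 0.052, 0.086, 28),
              neutropenia = c(0.020, 0.015, 0.025, 8)),
    chemo = list(hypertension = c(0.026, 0.020, 0.033, 10),
                 diarrhea = c(0.021, 0.016, 0.026, 8),
                 decreased_appetite = c(0.005, 0.004, 0.006, 2),
                 weight_loss = c(0.003, 0.002, 0.004, 1),
                 fatigue = c(0.031, 0.023, 0.039, 12),
                 proteinuria = c(0.003, 0.002, 0.004, 1),
                 anemia = c(0.155, 0.116, 0.194, 60),
                 neutropenia = c(0.260, 0.195, 0.325, 101)))
  denom <- c(lp = 406, chemo = 388)
  for (arm in names(risks)) {
    for (ev in names(risks[[arm]])) {
      r <- risks[[arm]][[ev]]
      add(name = paste0("risk_", ev, "_", arm), base = r[1],
          dsa_low = r[2], dsa_high = r[3], psa_family = "beta_counts",
          psa_pars = c(r[4], denom[[arm]]),
          set = set_ae_field(arm, ev, "risk"), support = c(0, 1))
    }
  }

  # utilities (shared between arms)
  add(name = "utility_pf", base = 0.817, dsa_low = 0.797,
      dsa_high = 0.836, psa_family = "beta_ab",
      psa_pars = c(73.53, 16.47), set = set_strategy_field(both,
      "utility_pf"), support = c(0, 1))
  add(name = "utility_pd", base = 0.779, dsa_low = 0.699,
      dsa_high = 0.859, psa_family = "beta_ab",
      psa_pars = c(70.11, 19.89), set = set_strategy_field(both,
      "utility_pd"), support = c(0, 1))

  # adverse-event disutilities (shared values)
  dis <- list(
    hypertension = list(0.050, 0.038, 0.063, c(95, 1804)),
    diarrhea = list(0.001, 0.001, 0.001, NULL),
    decreased_appetite = list(0.002, 0.002, 0.003, NULL),
    fatigue = list(0.070, 0.053, 0.088, NULL),
    anemia = list(0.073, 0.055, 0.091, c(93, 1176)),
    neutropenia = list(0.460, 0.345, 0.575, c(54, 63)))
  for (ev in names(dis)) {
    d <- dis[[ev]]
    shapes <- if (is.null(d[[4]])) {
      beta_from_moments(d[[1]], d[[1]] * 0.25 / 2)  # +/-25% as +/-2 sd
    } else d[[4]]
    add(name = paste0("disutility_", ev), base = d[[1]], dsa_low = d[[2]],
        dsa_high = d[[3]], psa_family = "beta_ab", psa_pars = shapes,
        set = set_ae_field(both, ev, "disutility"), support = c(0, 1))
  }

  # medication costs per cycle
  add(name = "cost_lenvatinib", base = 40656, dsa_low = 30492,
      dsa_high = 50820, psa_family = "uniform", psa_pars = c(1452, 2420),
      psa_scale = 21, set = set_med_cost("lp", "lenvatinib"),
      support = c(0, Inf))
  add(name = "cost_pembrolizumab", base = 98668, dsa_low = 74001,
      dsa_high = 123335, psa_family = "uniform",
      psa_pars = c(74001, 123335), set = set_med_cost("lp",
      "pembrolizumab"), support = c(0, Inf))
  add(name = "cost_doxorubicin", base = 3779, dsa_low = 2834,
      dsa_high = 4724, psa_family = "gamma_meansd",
      psa_pars = c(3779, 167), set = set_med_cost("chemo", "doxorubicin"),
      support = c(0, Inf))
  add(name = "cost_other_chemotherapy", base = 2999, dsa_low = 2249,
      dsa_high = 3749, psa_family = "gamma_meansd",
      psa_pars = c(2999, 671),
      set = set_med_cost("chemo", "other_chemotherapy"),
      support = c(0, Inf))

  # adverse-event management costs (shared values)
  ae_costs <- list(hypertension = c(28, 21, 35, 4),
                   diarrhea = c(25, 19, 31, 11),
                   decreased_appetite = c(524, 393, 655, 105),
                   weight_loss = c(562, 422, 703, 121),
                   anemia = c(674, 506, 843, 115),
                   neutropenia = c(2544, 1908, 3180, 564))
  for (ev in names(ae_costs)) {
    a <- ae_costs[[ev]]
    add(name = paste0("cost_ae_", ev), base = a[1], dsa_low = a[2],
        dsa_high = a[3], psa_family = "gamma_meansd",
        psa_pars = c(a[1], a[4]), set = set_ae_field(both, ev, "cost"),
        support = c(0, Inf))
  }

  # non-medication state costs (shared)
  add(name = "cost_pf_nonmed", base = 22149, dsa_low = 16612,
      dsa_high = 27686, psa_family = "gamma_meansd",
      psa_pars = c(22149, 2971), set = set_strategy_field(both,
      "pf_nonmed"), support = c(0, Inf))
  add(name = "cost_supportive_care", base = 49742, dsa_low = 37307,
      dsa_high = 62178, psa_family = "gamma_meansd",
      psa_pars = c(49742, 7309), set = set_strategy_field(both,
      "pd_cost"), support = c(0, Inf))

  names(sp) <- vapply(sp, `[[`, character(1), "name")
  sp
}

#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Draws are independent across parameters. Draws outside a parameter's
#' support are redrawn; the redraw count is reported in the
#' `"n_redraws"` attribute.
#'
#' @param params List of [param_spec()] objects.
#' @param n Number of draws.
#' @param seed Integer seed (draws are reproducible given the seed).
#' @return An `n` x `length(params)` matrix with parameter names as
#'   columns, on the model scale (i.e. `psa_scale` already applied).
#' @export
psa_sample <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  redraws <- 0L
  draw_one <- function(sp, m) {
    switch(sp$psa_family,
      normal = stats::rnorm(m, sp$psa_pars[1], sp$psa_pars[2]),
      beta_ab = stats::rbeta(m, sp$psa_pars[1], sp$psa_pars[2]),
      beta_counts = stats::rbeta(m, sp$psa_pars[1],
                                 sp$psa_pars[2] - sp$psa_pars[1]),
      uniform = stats::runif(m, sp$psa_pars[1], sp$psa_pars[2]),
      gamma_meansd = stats::rgamma(m,
        shape = (sp$psa_pars[1] / sp$psa_pars[2])^2,
        scale = sp$psa_pars[2]^2 / sp$psa_pars[1]),
      fixed = rep(sp$base / sp$psa_scale, m))
  }
  out <- matrix(NA_real_, n, length(params),
                dimnames = list(NULL, names(params)))
  for (j in seq_along(params)) {
    sp <- params[[j]]
    v <- draw_one(sp, n) * sp$psa_scale
    bad <- which(v <= sp$support[1] | v >= sp$support[2] | !is.finite(v))
    tries <- 0
    while (length(bad) && tries < 100) {
      redraws <- redraws + length(bad)
      v[bad] <- draw_one(sp, length(bad)) * sp$psa_scale
      bad <- which(v <= sp$support[1] | v >= sp$support[2] |
                     !is.finite(v))
      tries <- tries + 1
    }
    if (length(bad)) stop("param '", sp$name,
                          "': cannot draw within support")
    out[, j] <- v
  }
  if (redraws > 0) {
    warning(redraws, " out-of-support draw(s) redrawn")
  }
  attr(out, "n_redraws") <- redraws
  out
}

apply_param_vector <- function(cfg, params, values) {
  for (j in seq_along(params)) {
    cfg <- params[[j]]$set(cfg, unname(values[[j]]))
  }
  cfg
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full deterministic model with each parameter at its low
#' and high bound (all others at base) and records the incremental net
#' monetary benefit at each bound. A model failure at a bound flags the
#' entry instead of aborting.
#'
#' @param cfg A `model_config`.
#' @param params List of [param_spec()] objects.
#' @param wtp Threshold (default: the config's).
#' @return Data frame sorted by descending spread: `param`, `low`,
#'   `high`, `inmb_low`, `inmb_high`, `spread`, `failed`.
#' @export
dsa_oneway <- function(cfg, params = base_case_params(), wtp = NULL) {
  cfg <- validate_config(unclass(cfg))
  if (is.null(wtp)) wtp <- cfg$econ$wtp
  eval_at <- function(sp, v) {
    tryCatch(run_model(sp$set(cfg, v))$cea$inmb,
             error = function(e) NA_real_)
  }
  rows <- lapply(params, function(sp) {
    lo <- eval_at(sp, sp$dsa_low)
    hi <- eval_at(sp, sp$dsa_high)
    data.frame(param = sp$name, low = sp$dsa_low, high = sp$dsa_high,
               inmb_low = lo, inmb_high = hi,
               spread = abs(hi - lo),
               failed = is.na(lo) || is.na(hi))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$spread), , drop = FALSE]
}

#' Run the probabilistic sensitivity analysis
#'
#' One full two-strategy model evaluation per sampled parameter vector.
#'
#' @param cfg A `model_config`.
#' @param params List of [param_spec()] objects.
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed.
#' @return A `psa_draws` data frame: per draw, cost/QALY/LY for the
#'   intervention (`_int`) and comparator (`_comp`), plus the sampled
#'   parameter matrix as attribute `"samples"`. Per-draw failures are
#'   dropped with a warning (count in attribute `"n_failed"`).
#' @export
run_psa <- function(cfg, params = base_case_params(), n = 1000L,
                    seed = NULL) {
  cfg <- validate_config(unclass(cfg))
  econ <- do.call(econ_params, cfg$econ)
  draws_mat <- psa_sample(params, n, seed)
  res <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("cost_int", "qaly_int", "ly_int",
                                        "cost_comp", "qaly_comp",
                                        "ly_comp")))
  failed <- 0L
  for (i in seq_len(n)) {
    ri <- tryCatch({
      cfg_i <- apply_param_vector(cfg, params, draws_mat[i, ])
      strat <- build_strategies(cfg_i)
      s1 <- summarize_trace(run_trace(strat[[1]], econ))
      s2 <- summarize_trace(run_trace(strat[[2]], econ))
      c(s1$cost, s1$qaly, s1$ly, s2$cost, s2$qaly, s2$ly)
    }, error = function(e) NULL)
    if (is.null(ri)) failed <- failed + 1L else res[i, ] <- ri
  }
  if (failed > 0) {
    warning(failed, " PSA draw(s) failed and were excluded")
  }
  ok <- stats::complete.cases(res)
  out <- data.frame(draw = which(ok), res[ok, , drop = FALSE])
  attr(out, "samples") <- draws_mat
  attr(out, "n_failed") <- failed
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Build a scenario specification
#'
#' Overrides applied by [apply_scenario()]: time horizon, LP price
#' multiplier (intervention medication components only), discount rates,
#' the point-value conversion factor on non-medication, supportive-care
#' and adverse-event costs, and the effect measure.
#'
#' @param label Scenario name.
#' @param horizon_years,lp_price_multiplier,disc_effects,disc_costs,
#'   conversion_factor,outcome Optional overrides; `NULL` leaves the
#'   config value unchanged.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(label, horizon_years = NULL,
                          lp_price_multiplier = NULL, disc_effects = NULL,
                          disc_costs = NULL, conversion_factor = NULL,
                          outcome = NULL) {
  if (!is.null(lp_price_multiplier) && lp_price_multiplier <= 0) {
    stop("lp_price_multiplier must be > 0")
  }
  if (!is.null(outcome)) outcome <- match.arg(outcome, c("qaly", "ly"))
  structure(list(label = label, horizon_years = horizon_years,
                 lp_price_multiplier = lp_price_multiplier,
                 disc_effects = disc_effects, disc_costs = disc_costs,
                 conversion_factor = conversion_factor, outcome = outcome),
            class = "scenario_spec")
}

#' Apply a scenario to a configuration
#'
#' Pure transformation: unspecified overrides leave the config
#' untouched; price multipliers compose (applying `m` then `1/m`
#' restores the original).
#'
#' @param cfg A `model_config`.
#' @param scenario A [scenario_spec()].
#' @return The modified `model_config`.
#' @export
apply_scenario <- function(cfg, scenario) {
  cfg <- validate_config(unclass(cfg))
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(scenario$horizon_years)) {
    cfg$econ$horizon_years <- scenario$horizon_years
  }
  if (!is.null(scenario$lp_price_multiplier)) {
    cfg$lp_price_multiplier <- cfg$lp_price_multiplier *
      scenario$lp_price_multiplier
  }
  if (!is.null(scenario$disc_effects)) {
    cfg$econ$disc_effects <- scenario$disc_effects
  }
  if (!is.null(scenario$disc_costs)) {
    cfg$econ$disc_costs <- scenario$disc_costs
  }
  if (!is.null(scenario$conversion_factor)) {
    cfg$conversion_factor <- scenario$conversion_factor
  }
  if (!is.null(scenario$outcome)) cfg$outcome <- scenario$outcome
  validate_config(unclass(cfg))
}

#' The twelve standard scenarios
#'
#' Base case; life-years as the effect measure; 5-, 30-, 40- and 50-year
#' horizons; 90%, 80% and 70% LP pricing; 3.5% and 1.5% discount rates
#' (costs and effects together); and the 0.9 point-value conversion
#' factor.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
base_scenarios <- function() {
  list(
    base_case = scenario_spec("Base-case"),
    life_years = scenario_spec("Life years", outcome = "ly"),
    horizon_5y = scenario_spec("5-year time horizon", horizon_years = 5),
    horizon_30y = scenario_spec("30-year time horizon",
                                horizon_years = 30),
    horizon_40y = scenario_spec("40-year time horizon",
                                horizon_years = 40),
    horizon_50y = scenario_spec("50-year time horizon",
                                horizon_years = 50),
    price_90 = scenario_spec("90% price of LP",
                             lp_price_multiplier = 0.9),
    price_80 = scenario_spec("80% price of LP",
                             lp_price_multiplier = 0.8),
    price_70 = scenario_spec("70% price of LP",
                             lp_price_multiplier = 0.7),
    discount_3.5 = scenario_spec("3.5% discount rate",
                                 disc_effects = 0.035, disc_costs = 0.035),
    discount_1.5 = scenario_spec("1.5% discount rate",
                                 disc_effects = 0.015, disc_costs = 0.015),
    conversion_0.9 = scenario_spec("Conversion factor 0.9",
                                   conversion_factor = 0.9))
}

#' Deterministic (and optionally probabilistic) scenario table
#'
#' @param cfg A `model_config`.
#' @param scenarios List of [scenario_spec()] objects.
#' @param psa_n PSA iterations per scenario (0 = deterministic only).
#' @param seed Seed for the per-scenario PSA.
#' @param params Parameter set for the per-scenario PSA.
#' @return Data frame with one row per scenario: ICER, INMB and (when
#'   `psa_n > 0`) probability cost-effective and EVPI per person.
#' @export
scenario_table <- function(cfg, scenarios = base_scenarios(), psa_n = 0,
                           seed = 1L, params = base_case_params()) {
  cfg <- validate_config(unclass(cfg))
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    cfg_i <- apply_scenario(cfg, sc)
    res <- run_model(cfg_i)
    row <- data.frame(scenario = sc$label, icer = res$cea$icer,
                      icer_label = res$cea$icer_label,
                      inmb = res$cea$inmb)
    if (psa_n > 0) {
      dr <- run_psa(cfg_i, params, n = psa_n, seed = seed + i - 1L)
      row$prob_ce <- ceac(dr, cfg_i$econ$wtp, cfg_i$outcome)$prob_ce
      row$evpi_per_person <- evpi(dr, cfg_i$econ$wtp, cfg_i$outcome)
    }
    row
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
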