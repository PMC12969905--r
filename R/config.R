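#' Base-case model configuration
#'
#' The shipped configuration for the second-line advanced endometrial
#' carcinoma comparison: lenvatinib plus pembrolizumab (LP) versus
#' doxorubicin-based chemotherapy, priced and parameterized for Taiwan's
#' National Health Insurance. Survival: LP OS and PFS are log-normal
#' (meanlog 2.911 / sdlog 1.245 and 2.002 / 1.172); chemotherapy OS and
#' PFS are log-logistic (shape 1.683 / scale 11.905 and 1.885 / 3.956),
#' all in months. Medication per 21-day cycle: lenvatinib NT$40,656 and
#' pembrolizumab NT$98,668 (capped at 35 doses) for LP; doxorubicin
#' NT$3,779 and other chemotherapy NT$2,999 for the comparator.
#' Non-medication PF cost NT$22,149/cycle and supportive care
#' NT$49,742/cycle apply to both arms, as do utilities 0.817 (PF) and
#' 0.779 (PD). Adverse-event risks are arm-specific; management costs and
#' disutilities are shared (fatigue and proteinuria incur no cost;
#' weight loss and proteinuria carry no disutility).
#'
#' @return A `model_config` list with elements `strategies` (named list
#'   of two strategy blocks, intervention first), `econ`,
#'   `conversion_factor`, `lp_price_multiplier` and `outcome`.
#' @export
base_case_config <- function() {
  ae_names <- c("hypertension", "diarrhea", "decreased_appetite",
                "weight_loss", "fatigue", "proteinuria", "anemia",
                "neutropenia")
  ae_cost <- c(28, 25, 524, 562, 0, 0, 674, 2544)
  ae_disutil <- c(0.050, 0.001, 0.002, 0, 0.070, 0, 0.073, 0.460)
  lp_risk <- c(0.392, 0.081, 0.076, 0.108, 0.054, 0.052, 0.069, 0.020)
  ch_risk <- c(0.026, 0.021, 0.005, 0.003, 0.031, 0.003, 0.155, 0.260)

  cfg <- list(
    strategies = list(
      lp = list(
        name = "Lenvatinib plus pembrolizumab",
        os = list(family = "lognormal",
                  params = c(meanlog = 2.911, sdlog = 1.245)),
        pfs = list(family = "lognormal",
                   params = c(meanlog = 2.002, sdlog = 1.172)),
        med = data.frame(label = c("lenvatinib", "pembrolizumab"),
                         cost_per_cycle = c(40656, 98668),
                         max_cycles = c(Inf, 35)),
        pf_nonmed = 22149, pd_cost = 49742,
        utility_pf = 0.817, utility_pd = 0.779,
        ae = data.frame(name = ae_names, risk = lp_risk, cost = ae_cost,
                        disutility = ae_disutil)),
      chemo = list(
        name = "Doxorubicin-based chemotherapy",
        os = list(family = "loglogistic",
                  params = c(shape = 1.683, scale = 11.905)),
        pfs = list(family = "loglogistic",
                   params = c(shape = 1.885, scale = 3.956)),
        med = data.frame(label = c("doxorubicin", "other_chemotherapy"),
                         cost_per_cycle = c(3779, 2999),
                         max_cycles = c(Inf, Inf)),
        pf_nonmed = 22149, pd_cost = 49742,
        utility_pf = 0.817, utility_pd = 0.779,
        ae = data.frame(name = ae_names, risk = ch_risk, cost = ae_cost,
                        disutility = ae_disutil))),
    econ = list(cycle_days = 21, horizon_years = 20, disc_effects = 0.03,
                disc_costs = 0.03, wtp = 2917650),
    conversion_factor = 1,
    lp_price_multiplier = 1,
    outcome = "qaly")
  validate_config(cfg)
}

config_known_keys <- c("strategies", "econ", "conversion_factor",
                       "lp_price_multiplier", "outcome", "seed")
strategy_known_keys <- c("name", "os", "pfs", "med", "pf_nonmed",
                         "pd_cost", "utility_pf", "utility_pd", "ae")

#' Validate a model configuration
#'
#' Checks the structural invariants: exactly two strategies, known keys
#' only, valid survival families and parameters, non-negative costs,
#' utilities and risks in \[0, 1\], positive multipliers and a horizon of
#' at least one cycle. Errors name the offending field.
#'
#' @param cfg A configuration list.
#' @return The validated config, classed `model_config`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$strategies) || length(cfg$strategies) != 2) {
    stop("config must define exactly two strategies (intervention first)")
  }
  for (nm in names(cfg$strategies)) {
    s <- cfg$strategies[[nm]]
    unknown <- setdiff(names(s), strategy_known_keys)
    if (length(unknown)) {
      stop("strategy '", nm, "': unknown key(s) ",
           paste(unknown, collapse = ", "))
    }
    for (f in c("name", "os", "pfs", "med", "pf_nonmed", "pd_cost",
                "utility_pf", "utility_pd")) {
      if (is.null(s[[f]])) stop("strategy '", nm, "': missing field '", f, "'")
    }
    for (curve in c("os", "pfs")) {
      as_parsurv(s[[curve]])  # errors on bad family/params
    }
    med <- as.data.frame(s$med)
    if (!all(c("label", "cost_per_cycle", "max_cycles") %in% names(med))) {
      stop("strategy '", nm, "': med needs label/cost_per_cycle/max_cycles")
    }
    if (any(med$cost_per_cycle < 0)) {
      stop("strategy '", nm, "': negative medication cost")
    }
    if (s$utility_pf < 0 || s$utility_pf > 1 ||
        s$utility_pd < 0 || s$utility_pd > 1) {
      stop("strategy '", nm, "': utilities must be in [0, 1]")
    }
    if (s$pf_nonmed < 0 || s$pd_cost < 0) {
      stop("strategy '", nm, "': negative state cost")
    }
    if (!is.null(s$ae)) {
      ae <- as.data.frame(s$ae)
      if (any(ae$risk < 0 | ae$risk > 1)) {
        stop("strategy '", nm, "': AE risk outside [0, 1]")
      }
      if (any(ae$cost < 0) || any(ae$disutility < 0 | ae$disutility > 1)) {
        stop("strategy '", nm, "': invalid AE cost or disutility")
      }
    }
  }
  e <- cfg$econ
  for (f in c("cycle_days", "horizon_years", "disc_effects", "disc_costs",
              "wtp")) {
    if (is.null(e[[f]])) stop("econ: missing field '", f, "'")
  }
  do.call(econ_params, e)  # range checks
  if (is.null(cfg$conversion_factor)) cfg$conversion_factor <- 1
  if (is.null(cfg$lp_price_multiplier)) cfg$lp_price_multiplier <- 1
  if (is.null(cfg$outcome)) cfg$outcome <- "qaly"
  if (cfg$conversion_factor <= 0 || cfg$lp_price_multiplier <= 0) {
    stop("conversion_factor and lp_price_multiplier must be > 0")
  }
  cfg$outcome <- match.arg(cfg$outcome, c("qaly", "ly"))
  class(cfg) <- c("model_config", "list")
  cfg
}

#' Build strategy_spec objects from a configuration
#'
#' Applies the LP price multiplier (to the intervention's medication
#' components only) and the point-value conversion factor (to
#' non-medication PF costs, supportive care and adverse-event management
#' costs in both arms).
#'
#' @param cfg A validated `model_config`.
#' @return Named list of two [strategy_spec()] objects.
#' @export
build_strategies <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  cf <- cfg$conversion_factor
  out <- list()
  for (i in seq_along(cfg$strategies)) {
    s <- cfg$strategies[[i]]
    med <- as.data.frame(s$med)
    if (i == 1) {  # intervention: price multiplier applies
      med$cost_per_cycle <- med$cost_per_cycle * cfg$lp_price_multiplier
    }
    ae <- as.data.frame(s$ae)
    out[[names(cfg$strategies)[i]]] <- strategy_spec(
      name = s$name,
      os = as_parsurv(s$os), pfs = as_parsurv(s$pfs),
      med = med,
      pf_nonmed = s$pf_nonmed * cf,
      pd_cost = s$pd_cost * cf,
      utility_pf = s$utility_pf, utility_pd = s$utility_pd,
      ae = ae_profile(ae$name, ae$risk, ae$cost * cf, ae$disutility))
  }
  out
}

#' Run the deterministic two-strategy model
#'
#' @param cfg A `model_config`.
#' @param half_cycle Passed to [run_trace()].
#' @return List with `traces` (per strategy), `summary` (two-row data
#'   frame of totals) and `cea` (a [cea_result()] using the config's
#'   outcome measure and WTP).
#' @export
run_model <- function(cfg, half_cycle = FALSE) {
  cfg <- validate_config(unclass(cfg))
  econ <- do.call(econ_params, cfg$econ)
  strat <- build_strategies(cfg)
  traces <- lapply(strat, run_trace, econ = econ, half_cycle = half_cycle)
  summaries <- lapply(traces, summarize_trace)
  list(traces = traces,
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       cea = cea_result(summaries[[1]], summaries[[2]], wtp = econ$wtp,
                        effect = cfg$outcome))
}

#' Read a model configuration from a YAML file
#'
#' @param path File path.
#' @return A validated `model_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (nm in names(raw$strategies)) {
    s <- raw$strategies[[nm]]
    for (f in c("med", "ae")) {
      if (!is.null(s[[f]])) {
        df <- as.data.frame(lapply(s[[f]], unlist),
                            stringsAsFactors = FALSE)
        if (f == "med" && is.character(df$max_cycles)) {
          df$max_cycles <- as.numeric(ifelse(df$max_cycles %in%
                                               c("Inf", ".inf"), Inf,
                                             df$max_cycles))
        }
        raw$strategies[[nm]][[f]] <- df
      }
    }
    for (curve in c("os", "pfs")) {
      if (!is.null(s[[curve]])) {
        raw$strategies[[nm]][[curve]]$params <-
          unlist(s[[curve]]$params)
      }
    }
  }
  validate_config(raw)
}

#' Write a model configuration to a YAML file
#'
#' @param cfg A `model_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path) {
  cfg <- validate_config(unclass(cfg))
  ser <- unclass(cfg)
  for (nm in names(ser$strategies)) {
    s <- ser$strategies[[nm]]
    med <- as.data.frame(s$med)
    med$max_cycles <- ifelse(is.infinite(med$max_cycles), "Inf",
                             as.character(med$max_cycles))
    ser$strategies[[nm]]$med <- lapply(as.list(med), as.vector)
    ser$strategies[[nm]]$ae <- lapply(as.list(as.data.frame(s$ae)),
                                      as.vector)
    for (curve in c("os", "pfs")) {
      ser$strategies[[nm]][[curve]]$params <-
        as.list(s[[curve]]$params)
    }
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Hash of a configuration (for run manifests)
#'
#' MD5 of the canonical YAML serialization.
#'
#' @param cfg A `model_config`.
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_model_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline and write result tables
#'
#' Thin orchestration over the package's functions: `"run"` writes the
#' deterministic base-case table (totals with PF/PD splits, ICER per
#' QALY and per life-year, INMB), `"fit"` refits the six families to
#' supplied IPD, `"dsa"` writes the one-way tornado table, `"psa"`
#' writes per-draw results, the CEAC grid and the EVPI, and
#' `"scenarios"` writes the scenario table. A manifest (config hash,
#' seed, package version) accompanies the outputs.
#'
#' @param cfg A `model_config`.
#' @param commands Subset of `c("fit", "run", "dsa", "psa", "scenarios")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the stochastic commands.
#' @param n_psa Number of PSA iterations.
#' @param ipd Optional named list of IPD data frames for `"fit"`.
#' @param scenarios Scenario list for `"scenarios"`
#'   (default [base_scenarios()]).
#' @param psa_in_scenarios Run a PSA inside each scenario (slower).
#' @return Invisible list of the objects written.
#' @export
run_pipeline <- function(cfg, commands = "run", out_dir = ".",
                         seed = 1L, n_psa = 1000L, ipd = NULL,
                         scenarios = base_scenarios(),
                         psa_in_scenarios = FALSE) {
  cfg <- validate_config(unclass(cfg))
  commands <- match.arg(commands,
                        c("fit", "run", "dsa", "psa", "scenarios"),
                        several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  wtp <- cfg$econ$wtp

  if ("run" %in% commands) {
    res <- run_model(cfg)
    tab <- base_case_table(res, wtp)
    utils::write.csv(tab, file.path(out_dir, "base_case.csv"),
                     row.names = FALSE)
    out$base_case <- tab
  }
  if ("fit" %in% commands) {
    if (is.null(ipd)) stop("'fit' needs a named list of IPD data frames")
    fits <- do.call(rbind, lapply(names(ipd), function(nm) {
      tab <- fit_table(rank_models(ipd[[nm]]))
      cbind(dataset = nm, tab)
    }))
    utils::write.csv(fits, file.path(out_dir, "survival_fits.csv"),
                     row.names = FALSE)
    out$fits <- fits
  }
  if ("dsa" %in% commands) {
    tor <- dsa_oneway(cfg, base_case_params())
    utils::write.csv(tor, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    out$tornado <- tor
  }
  if ("psa" %in% commands) {
    draws <- run_psa(cfg, base_case_params(), n = n_psa, seed = seed)
    utils::write.csv(draws, file.path(out_dir, "psa_draws.csv"),
                     row.names = FALSE)
    grid <- seq(0, 2 * wtp, length.out = 41)
    cc <- ceac(draws, grid, effect = cfg$outcome)
    utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
    psum <- data.frame(wtp = wtp,
                       prob_ce = ceac(draws, wtp, cfg$outcome)$prob_ce,
                       evpi_per_person = evpi(draws, wtp, cfg$outcome))
    utils::write.csv(psum, file.path(out_dir, "psa_summary.csv"),
                     row.names = FALSE)
    out$psa <- list(draws = draws, ceac = cc, summary = psum)
  }
  if ("scenarios" %in% commands) {
    sc <- scenario_table(cfg, scenarios, psa_n = if (psa_in_scenarios)
      n_psa else 0, seed = seed)
    utils::write.csv(sc, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
    out$scenarios <- sc
  }

  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   n_psa = n_psa, commands = commands,
                   package_version =
                     as.character(utils::packageVersion("psmcea")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Deterministic results in the layout of a base-case table
#'
#' @param res Output of [run_model()].
#' @param wtp Willingness-to-pay threshold.
#' @return Data frame with one row per quantity (costs, LYs, QALYs with
#'   PF/PD splits, ICERs and INMBs per QALY and per life-year) and one
#'   column per strategy plus the incremental column.
#' @export
base_case_table <- function(res, wtp) {
  s <- res$summary
  ceq <- cea_result(s[1, ], s[2, ], wtp, "qaly")
  cel <- cea_result(s[1, ], s[2, ], wtp, "ly")
  row <- function(q, digits = 2) {
    c(s[[q]][1], s[[q]][2], s[[q]][1] - s[[q]][2])
  }
  m <- rbind(cost = row("cost"), cost_pf = row("cost_pf"),
             cost_pd = row("cost_pd"),
             ly = row("ly"), ly_pf = row("ly_pf"), ly_pd = row("ly_pd"),
             qaly = row("qaly"), qaly_pf = row("qaly_pf"),
             qaly_pd = row("qaly_pd"),
             icer_per_ly = c(NA, NA, cel$icer),
             icer_per_qaly = c(NA, NA, ceq$icer),
             inmb_ly = c(NA, NA, cel$inmb),
             inmb_qaly = c(NA, NA, ceq$inmb))
  out <- data.frame(quantity = rownames(m), m, row.names = NULL)
  names(out)[2:4] <- c(s$strategy[1], s$strategy[2], "incremental")
  out
}
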