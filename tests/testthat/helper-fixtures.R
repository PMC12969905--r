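# Shared fixtures: everything is generated in code at test time.

# A short-horizon economic frame for fast engine tests.
quick_econ <- function(...) {
  econ_params(horizon_years = 1, ...)
}

# A minimal strategy with constant survival and clean round numbers.
flat_strategy <- function(os = function(t) rep(1, length(t)),
                          pfs = function(t) rep(1, length(t)),
                          med_cost = 0, max_cycles = Inf,
                          pf_nonmed = 0, pd_cost = 0,
                          utility_pf = 1, utility_pd = 1,
                          ae = ae_profile()) {
  strategy_spec(name = "flat", os = os, pfs = pfs,
                med = data.frame(label = "drug",
                                 cost_per_cycle = med_cost,
                                 max_cycles = max_cycles),
                pf_nonmed = pf_nonmed, pd_cost = pd_cost,
                utility_pf = utility_pf, utility_pd = utility_pd, ae = ae)
}

# Exact KM inputs for round-trip reconstruction checks.
km_inputs_from_ipd <- function(ipd) {
  km <- km_estimate(ipd)
  list(curve = data.frame(time = km$time, survival = km$survival),
       risk = data.frame(time = c(0, km$time),
                         n_risk = c(nrow(ipd), km$n_risk)))
}
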