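test_that("state membership partitions the cohort", {
  os <- function(t) rep(0.7, length(t))
  pfs <- function(t) rep(0.4, length(t))
  m <- state_membership(os, pfs, 1)
  expect_equal(unlist(m), c(pf = 0.4, pd = 0.3, dead = 0.3))

  # at t = 0 everyone is progression-free
  m0 <- state_membership(parametric_survival("exponential", 0.1),
                         parametric_survival("exponential", 0.3), 0)
  expect_equal(unlist(m0), c(pf = 1, pd = 0, dead = 0))

  # crossing curves are clamped: PFS above OS gives PD = 0
  mx <- state_membership(function(t) rep(0.7, length(t)),
                         function(t) rep(0.8, length(t)), 2)
  expect_equal(unlist(mx), c(pf = 0.7, pd = 0, dead = 0.3))
  expect_equal(attr(mx, "n_clamped"), 1)
})

test_that("degenerate trace accrues exactly K cycles of life", {
  econ <- econ_params(horizon_years = 1, disc_effects = 0,
                      disc_costs = 0)
  tr <- run_trace(flat_strategy(), econ)
  K <- floor(365.25 / 21)
  expect_equal(K, 17)
  s <- summarize_trace(tr)
  expect_equal(s$ly, K * 21 / 365.25)
  expect_equal(s$qaly, s$ly)
  expect_equal(s$cost, 0)
})

test_that("discounting matches a direct summation oracle", {
  econ <- econ_params(horizon_years = 1)
  tr <- run_trace(flat_strategy(), econ)
  k <- 1:17
  oracle <- sum(1.03^(-(k * 21 / 365.25)) * 21 / 365.25)
  expect_equal(summarize_trace(tr)$ly, oracle)
  # discounted totals are strictly below undiscounted ones
  tr0 <- run_trace(flat_strategy(),
                   econ_params(horizon_years = 1, disc_effects = 0,
                               disc_costs = 0))
  expect_lt(summarize_trace(tr)$ly, summarize_trace(tr0)$ly)
})

test_that("memberships normalize and death is absorbing", {
  strat <- build_strategies(base_case_config())
  for (tr in lapply(strat, run_trace)) {
    expect_equal(tr$pf + tr$pd + tr$dead, rep(1, nrow(tr)),
                 tolerance = 1e-12)
    expect_true(all(tr$pf >= 0 & tr$pf <= 1))
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
})

test_that("utility one makes QALYs equal life-years", {
  cfg <- base_case_config()
  for (a in names(cfg$strategies)) {
    cfg$strategies[[a]]$utility_pf <- 1
    cfg$strategies[[a]]$utility_pd <- 1
    cfg$strategies[[a]]$ae$disutility <- 0
  }
  s <- run_model(cfg)$summary
  expect_equal(s$qaly, s$ly)
})

test_that("total cost is linear in the cost inputs", {
  cfg <- base_case_config()
  base <- run_model(cfg)$summary
  for (a in names(cfg$strategies)) {
    s <- cfg$strategies[[a]]
    s$med$cost_per_cycle <- 2 * s$med$cost_per_cycle
    s$pf_nonmed <- 2 * s$pf_nonmed
    s$pd_cost <- 2 * s$pd_cost
    s$ae$cost <- 2 * s$ae$cost
    cfg$strategies[[a]] <- s
  }
  doubled <- run_model(cfg)$summary
  expect_equal(doubled$cost, 2 * base$cost)
  expect_equal(doubled$qaly, base$qaly)  # effects untouched
})

test_that("zero discounting dominates the discounted run component-wise", {
  cfg <- base_case_config()
  disc <- run_model(cfg)$summary
  cfg$econ$disc_effects <- 0
  cfg$econ$disc_costs <- 0
  undisc <- run_model(cfg)$summary
  for (col in c("cost", "cost_pf", "cost_pd", "ly", "ly_pf", "ly_pd",
                "qaly", "qaly_pf", "qaly_pd")) {
    expect_true(all(undisc[[col]] >= disc[[col]]), info = col)
  }
})

test_that("the pembrolizumab cap limits its contribution to 35 cycles", {
  cfg <- base_case_config()
  strat <- build_strategies(cfg)
  econ <- do.call(econ_params, cfg$econ)
  with_cap <- run_trace(strat$lp, econ)

  # same strategy with the cap removed: cost must differ only after
  # cycle 35, by exactly the pembrolizumab component
  cfg$strategies$lp$med$max_cycles <- c(Inf, Inf)
  no_cap <- run_trace(build_strategies(cfg)$lp, econ)
  expect_equal(with_cap$cost_med[1:35], no_cap$cost_med[1:35])
  post <- with_cap$cycle > 35
  pem <- 98668
  expect_equal(no_cap$cost_med[post] - with_cap$cost_med[post],
               pem * no_cap$pf[post] *
                 (1.03)^(-(no_cap$cycle[post] * 21 / 365.25)))
})

test_that("adverse events hit cost and QALYs once, in cycle one", {
  ae <- ae_profile(name = c("a", "b"), risk = c(0.5, 0.2),
                   cost = c(1000, 0), disutility = c(0.1, 0.4))
  econ <- econ_params(horizon_years = 1, disc_effects = 0,
                      disc_costs = 0)
  tr <- run_trace(flat_strategy(ae = ae), econ)
  expect_equal(tr$cost_ae, c(500, rep(0, 16)))
  expect_equal(tr$qaly_ae_loss,
               c((0.5 * 0.1 + 0.2 * 0.4) * 21 / 365.25, rep(0, 16)))
  s <- summarize_trace(tr)
  expect_equal(s$qaly, s$ly - (0.5 * 0.1 + 0.2 * 0.4) * 21 / 365.25)
})

test_that("trace summary splits add up to the totals", {
  res <- run_model(base_case_config())
  s <- res$summary
  expect_equal(s$cost, s$cost_pf + s$cost_pd)
  expect_equal(s$ly, s$ly_pf + s$ly_pd)
  expect_equal(s$qaly, s$qaly_pf + s$qaly_pd)
  # progressed-disease costs dominate progression-free in the
  # comparator arm (supportive care over a long PD phase)
  expect_gt(s$cost_pd[2], s$cost_pf[2])
})

test_that("horizon shorter than one cycle errors", {
  expect_error(econ_params(horizon_years = 0.01),
               "horizon")
})
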