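test_that("sampling distributions match their analytic moments", {
  params <- base_case_params()
  n <- 50000
  s <- psa_sample(params, n, seed = 17)

  # gamma by mean/sd: sample mean within 3 standard errors of the mean
  m <- mean(s[, "cost_doxorubicin"])
  se <- 167 / sqrt(n)
  expect_lt(abs(m - 3779), 3 * se)

  # beta shape pair: mean alpha/(alpha+beta) = 73.53/90
  expect_lt(abs(mean(s[, "utility_pf"]) - 73.53 / 90), 0.002)

  # beta from counts: mean events/n = 159/406 = printed risk 0.392
  expect_equal(159 / 406, 0.392, tolerance = 1e-3)
  expect_lt(abs(mean(s[, "risk_hypertension_lp"]) - 159 / 406), 0.003)

  # lenvatinib is sampled per day and scaled to the 21-day cycle
  expect_lt(abs(mean(s[, "cost_lenvatinib"]) - 21 * (1452 + 2420) / 2),
            3 * 21 * (2420 - 1452) / sqrt(12) / sqrt(n))
  expect_true(all(s[, "cost_lenvatinib"] >= 21 * 1452 &
                    s[, "cost_lenvatinib"] <= 21 * 2420))
})

test_that("draws respect each family's support", {
  params <- base_case_params()
  s <- psa_sample(params, 2000, seed = 2)
  beta_cols <- grep("^(risk_|disutility_|utility_)", colnames(s))
  expect_true(all(s[, beta_cols] > 0 & s[, beta_cols] < 1))
  cost_cols <- grep("^cost_", colnames(s))
  expect_true(all(s[, cost_cols] > 0))
  expect_true(all(s[, "lp_os_sdlog"] > 0))
  expect_true(all(s[, "chemo_os_scale"] > 0))
})

test_that("sampling is reproducible under a fixed seed", {
  params <- base_case_params()
  a <- psa_sample(params, 50, seed = 123)
  b <- psa_sample(params, 50, seed = 123)
  expect_identical(a, b)
})

test_that("param_spec validates its inputs", {
  expect_error(param_spec("x", 1, 2, 3, "normal", c(0, 1),
                          set = identity), "dsa_low")
  expect_error(param_spec("x", 1, 0, 2, "normal", c(1, -1),
                          set = identity), "invalid")
  expect_error(param_spec("x", 1, 0, 2, "beta_counts", c(10, 5),
                          set = identity), "invalid")
})

test_that("one-way DSA brackets the base case for monotone parameters", {
  cfg <- base_case_config()
  params <- base_case_params()
  tor <- dsa_oneway(cfg, params[c("cost_pembrolizumab",
                                  "cost_supportive_care", "utility_pd")])
  base_inmb <- run_model(cfg)$cea$inmb
  for (i in seq_len(nrow(tor))) {
    lo <- min(tor$inmb_low[i], tor$inmb_high[i])
    hi <- max(tor$inmb_low[i], tor$inmb_high[i])
    expect_lte(lo, base_inmb + 1e-6)
    expect_gte(hi, base_inmb - 1e-6)
  }
  # raising the intervention's drug price must lower its INMB
  pem <- tor[tor$param == "cost_pembrolizumab", ]
  expect_lt(pem$inmb_high, pem$inmb_low)
})

test_that("degenerate DSA ranges give zero spread and LP price ranks high", {
  cfg <- base_case_config()
  degen <- param_spec("frozen", 98668, 98668, 98668, "fixed",
                      set = set_med_cost("lp", "pembrolizumab"))
  tor <- dsa_oneway(cfg, list(frozen = degen))
  expect_equal(tor$spread, 0)

  full <- dsa_oneway(cfg, base_case_params())
  expect_true(all(diff(full$spread) <= 1e-9))  # sorted descending
  # the LP medication prices are among the top uncertainty drivers
  expect_true(all(c("cost_pembrolizumab", "cost_lenvatinib") %in%
                    full$param[1:12]))
})

test_that("degenerate PSA reproduces the deterministic run", {
  cfg <- base_case_config()
  params <- base_case_params()
  degen <- lapply(params, function(sp) {
    param_spec(sp$name, sp$base, sp$dsa_low, sp$dsa_high, "fixed",
               set = sp$set, psa_scale = sp$psa_scale)
  })
  dr <- run_psa(cfg, degen, n = 1, seed = 1)
  det <- run_model(cfg)$summary
  expect_equal(dr$cost_int, det$cost[1])
  expect_equal(dr$qaly_int, det$qaly[1])
  expect_equal(dr$cost_comp, det$cost[2])
  expect_equal(dr$ly_comp, det$ly[2])
})

test_that("PSA runs are seed-reproducible", {
  cfg <- base_case_config()
  params <- base_case_params()
  a <- run_psa(cfg, params, n = 10, seed = 7)
  b <- run_psa(cfg, params, n = 10, seed = 7)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("scenario engine applies and inverts overrides", {
  cfg <- base_case_config()
  # identity scenario changes nothing
  same <- apply_scenario(cfg, scenario_spec("identity"))
  expect_equal(unclass(same), unclass(cfg))

  # 0.8 price multiplier scales only LP medication
  s8 <- apply_scenario(cfg, scenario_spec("p80",
                                          lp_price_multiplier = 0.8))
  strat <- build_strategies(s8)
  expect_equal(sum(strat$lp$med$cost_per_cycle),
               0.8 * (40656 + 98668))
  expect_equal(sum(strat$chemo$med$cost_per_cycle), 3779 + 2999)

  # conversion factor 0.9 scales non-medication costs
  s9 <- apply_scenario(cfg, scenario_spec("cf", conversion_factor = 0.9))
  st9 <- build_strategies(s9)
  expect_equal(st9$lp$pf_nonmed, 0.9 * 22149)
  expect_equal(st9$lp$pd_cost, 0.9 * 49742)
  expect_equal(st9$chemo$ae$cost,
               0.9 * build_strategies(cfg)$chemo$ae$cost)

  # applying a multiplier and its inverse restores the original
  back <- apply_scenario(s8, scenario_spec("undo",
                                           lp_price_multiplier = 1.25))
  expect_equal(back$lp_price_multiplier, 1)
  expect_equal(unclass(back), unclass(cfg))

  expect_error(scenario_spec("bad", lp_price_multiplier = -1), "> 0")
})
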