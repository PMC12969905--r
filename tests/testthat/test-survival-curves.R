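test_that("closed-form survival values match known points", {
  # log-logistic median equals its scale parameter
  ll <- parametric_survival("loglogistic", c(shape = 1.683,
                                             scale = 11.905))
  expect_equal(surv_prob(ll, 11.905), 0.5)
  expect_equal(median_survival(ll), 11.905)

  # S(0) = 1 across all families
  models <- list(
    parametric_survival("exponential", 0.3),
    parametric_survival("weibull", c(1.4, 10)),
    parametric_survival("gompertz", c(0.05, 0.04)),
    ll,
    parametric_survival("lognormal", c(2.911, 1.245)),
    parametric_survival("gengamma", c(2.5, 1.1, 0.7)))
  for (m in models) expect_equal(surv_prob(m, 0), 1)

  # frozen value computed by trapezoid quadrature of the standard normal
  # density (independent of plnorm)
  ln <- parametric_survival("lognormal", c(2.911, 1.245))
  expect_equal(surv_prob(ln, 12), 0.6339162326, tolerance = 1e-7)
})

test_that("median survival agrees with closed forms and bisection", {
  expect_equal(median_survival(parametric_survival("loglogistic",
                                                   c(1.885, 3.956))),
               3.956)
  expect_equal(median_survival(parametric_survival("exponential",
                                                   log(2))), 1.0)

  # bisection oracle on the survival function itself
  ln <- parametric_survival("lognormal", c(2.002, 1.172))
  bisect <- function(f, lo, hi, tol = 1e-10) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0.5) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  oracle <- bisect(function(t) surv_prob(ln, t), 0, 100)
  expect_equal(median_survival(ln), exp(2.002), tolerance = 1e-8)
  expect_equal(oracle, exp(2.002), tolerance = 1e-6)

  # gompertz goes through the numeric branch; check S(median) = 0.5
  gp <- parametric_survival("gompertz", c(0.08, 0.05))
  expect_equal(surv_prob(gp, median_survival(gp)), 0.5, tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  expect_error(parametric_survival("loglogistic", c(-1, 5)), "parameter")
  expect_error(parametric_survival("lognormal", 2.9), "2 parameters")
  expect_error(surv_prob(parametric_survival("exponential", 1), -1),
               "domain")
})

test_that("survival curves are monotone, bounded and vanish at infinity", {
  set.seed(41)
  grid <- seq(0, 400, length.out = 1000)
  for (fam in psm_families()) {
    for (rep in 1:5) {
      params <- switch(fam,
        exponential = runif(1, 0.01, 1),
        weibull = runif(2, c(0.3, 1), c(3, 40)),
        gompertz = c(runif(1, 0.01, 0.3), runif(1, 0.005, 0.2)),
        loglogistic = runif(2, c(0.5, 1), c(4, 40)),
        lognormal = c(runif(1, 0, 3.5), runif(1, 0.3, 2)),
        gengamma = c(runif(1, 0, 3), runif(1, 0.3, 1.5),
                     runif(1, -1.5, 1.5)))
      m <- parametric_survival(fam, params)
      s <- surv_prob(m, grid)
      expect_true(all(diff(s) <= 1e-12), info = fam)
      expect_true(all(s >= 0 & s <= 1), info = fam)
      expect_lt(surv_prob(m, 1e6), 1e-6)
    }
  }
  # defective Gompertz (negative shape) plateaus instead
  gdef <- parametric_survival("gompertz", c(-0.1, 0.05))
  expect_gt(surv_prob(gdef, 1e6), 0)
  expect_equal(median_survival(gdef), Inf)
})

test_that("density matches the numerical derivative of -S", {
  h <- 1e-5
  grid <- seq(0.5, 60, length.out = 40)
  models <- list(
    parametric_survival("weibull", c(1.7, 12)),
    parametric_survival("lognormal", c(2.911, 1.245)),
    parametric_survival("loglogistic", c(1.683, 11.905)),
    parametric_survival("gompertz", c(0.06, 0.03)),
    parametric_survival("gengamma", c(2.4, 1.0, 0.5)))
  for (m in models) {
    num <- -(surv_prob(m, grid + h) - surv_prob(m, grid - h)) / (2 * h)
    expect_equal(num, surv_dens(m, grid), tolerance = 1e-4,
                 info = m$family)
  }
})

test_that("exponential MLE equals the closed form events/follow-up", {
  set.seed(5)
  ipd <- simulate_ipd(parametric_survival("exponential", 0.12), 300,
                      "uniform", cens_max = 25)
  fit <- fit_mle(ipd, "exponential")
  closed <- sum(ipd$event) / sum(ipd$time)
  expect_equal(unname(fit$model$params["rate"]), closed,
               tolerance = 1e-8)
  # information-criterion identities
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$bic, log(nrow(ipd)) - 2 * fit$loglik)
})

test_that("MLE recovers lognormal truth within 3 standard errors", {
  truth <- c(2.911, 1.245)
  ipd <- simulate_ipd(parametric_survival("lognormal", truth), 2000,
                      "uniform", cens_max = 5 * exp(truth[1]), seed = 23)
  expect_gt(mean(ipd$event == 0), 0.1)  # meaningful censoring present
  fit <- fit_mle(ipd, "lognormal")
  for (i in 1:2) {
    expect_lt(abs(fit$model$params[i] - truth[i]), 3 * fit$param_se[i])
  }
})

test_that("parameter bias shrinks as the sample grows", {
  truth <- c(2.0, 1.1)
  err <- vapply(c(500, 5000), function(n) {
    ipd <- simulate_ipd(parametric_survival("lognormal", truth), n,
                        "administrative", cens_time = 40, seed = 99)
    fit <- fit_mle(ipd, "lognormal")
    sqrt(sum((fit$model$params - truth)^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("information criteria rank the generating family first", {
  ipd <- simulate_ipd(parametric_survival("lognormal", c(2.911, 1.245)),
                      2000, "none", seed = 31)
  ranked <- rank_models(ipd, c("lognormal", "exponential"))
  expect_s3_class(ranked[[1]], "fit_report")
  expect_equal(ranked[[1]]$family, "lognormal")

  wb <- simulate_ipd(parametric_survival("weibull", c(2, 12)), 2000,
                     "none", seed = 32)
  rw <- rank_models(wb, c("weibull", "exponential"))
  expect_lt(rw[["weibull"]]$aic, rw[["exponential"]]$aic)
  expect_lt(rw[["weibull"]]$bic, rw[["exponential"]]$bic)

  # single family: trivially first; ranking is a permutation of fits
  one <- rank_models(ipd, "weibull")
  expect_equal(one[[1]]$family, "weibull")
  full <- rank_models(ipd, c("exponential", "weibull", "lognormal"))
  expect_setequal(vapply(full, `[[`, character(1), "family"),
                  c("exponential", "weibull", "lognormal"))
})

test_that("degenerate data and zero times are handled", {
  allcens <- data.frame(time = 1:10, event = 0)
  expect_error(fit_mle(allcens, "exponential"), "fit error")
  withzero <- data.frame(time = c(0, 1, 2, 3), event = 1)
  expect_warning(fit <- fit_mle(withzero, "exponential"), "shifted")
  expect_gt(fit$model$params["rate"], 0)
})
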