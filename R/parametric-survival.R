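#' Parametric survival distributions
#'
#' Constructor for the six parametric time-to-event families used for
#' survival extrapolation in health-economic models. Time is measured in
#' months (1 month = 30.4375 days). Parameterizations follow the
#' conventions standard in survival extrapolation practice:
#'
#' * `exponential`: `rate` (> 0), S(t) = exp(-rate t)
#' * `weibull`: `shape`, `scale` (> 0), S(t) = exp(-(t/scale)^shape)
#' * `gompertz`: `shape` (any real), `rate` (> 0),
#'   S(t) = exp(-(rate/shape)(e^(shape t) - 1)); a negative shape gives a
#'   defective (plateauing) tail
#' * `loglogistic`: `shape`, `scale` (> 0), S(t) = 1/(1 + (t/scale)^shape)
#' * `lognormal`: `meanlog` (any real), `sdlog` (> 0),
#'   S(t) = 1 - Phi((log t - meanlog)/sdlog)
#' * `gengamma`: generalized gamma in the (`mu`, `sigma`, `Q`)
#'   parameterization (`sigma` > 0)
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"gengamma"`.
#' @param params Numeric vector of parameters in the order listed above.
#'   Names, if given, must match the family's parameter names.
#' @return An object of class `parsurv`.
#' @examples
#' m <- parametric_survival("loglogistic", c(shape = 1.683, scale = 11.905))
#' surv_prob(m, c(0, 11.905))
#' @export
parametric_survival <- function(family, params) {
  family <- match.arg(family, psm_families())
  pn <- parsurv_param_names(family)
  params <- as.numeric(params)
  if (length(params) != length(pn)) {
    stop("family '", family, "' needs ", length(pn), " parameters (",
         paste(pn, collapse = ", "), "), got ", length(params))
  }
  names(params) <- pn
  check_parsurv_params(family, params)
  structure(list(family = family, params = params, time_unit = "months"),
            class = "parsurv")
}

#' @export
print.parsurv <- function(x, ...) {
  cat("<parsurv> ", x$family, "(",
      paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      "), time in months\n", sep = "")
  invisible(x)
}

#' Supported parametric survival families
#' @return Character vector of family names.
#' @export
psm_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal",
    "gengamma")
}

parsurv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    loglogistic = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"),
    gengamma    = c("mu", "sigma", "Q"))
}

# parameters that must be strictly positive (scale-type); others are free
parsurv_positive <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = "rate",
    loglogistic = c("shape", "scale"),
    lognormal   = "sdlog",
    gengamma    = "sigma")
}

check_parsurv_params <- function(family, params) {
  if (any(!is.finite(params))) {
    stop("non-finite parameter for family '", family, "'")
  }
  pos <- parsurv_positive(family)
  bad <- pos[params[pos] <= 0]
  if (length(bad)) {
    stop("parameter error: ", paste(bad, collapse = ", "),
         " must be > 0 for family '", family, "'")
  }
  invisible(TRUE)
}

as_parsurv <- function(x) {
  if (inherits(x, "parsurv")) return(x)
  if (is.list(x) && !is.null(x$family) && !is.null(x$params)) {
    return(parametric_survival(x$family, unlist(x$params)))
  }
  stop("cannot interpret object as a parametric survival model")
}

#' Survival function S(t)
#'
#' @param model A `parsurv` object (or list with `family` and `params`).
#' @param t Non-negative times in months (vectorized).
#' @return Survival probabilities in \[0, 1\].
#' @export
surv_prob <- function(model, t) {
  model <- as_parsurv(model)
  t <- as.numeric(t)
  if (any(is.na(t)) || any(t < 0)) {
    stop("domain error: t must be >= 0")
  }
  p <- model$params
  s <- switch(model$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-(t / p[["scale"]])^p[["shape"]]),
    gompertz    = 1 - flexsurv::pgompertz(t, shape = p[["shape"]],
                                          rate = p[["rate"]]),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal   = stats::plnorm(t, meanlog = p[["meanlog"]],
                                sdlog = p[["sdlog"]], lower.tail = FALSE),
    gengamma    = 1 - flexsurv::pgengamma(t, mu = p[["mu"]],
                                          sigma = p[["sigma"]],
                                          Q = p[["Q"]]))
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Density f(t) of the event-time distribution
#'
#' @inheritParams surv_prob
#' @return Density values.
#' @export
surv_dens <- function(model, t) {
  model <- as_parsurv(model)
  t <- as.numeric(t)
  if (any(t < 0)) stop("domain error: t must be >= 0")
  p <- model$params
  d <- switch(model$family,
    exponential = stats::dexp(t, rate = p[["rate"]]),
    weibull     = stats::dweibull(t, shape = p[["shape"]],
                                  scale = p[["scale"]]),
    gompertz    = flexsurv::dgompertz(t, shape = p[["shape"]],
                                      rate = p[["rate"]]),
    loglogistic = flexsurv::dllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]]),
    lognormal   = stats::dlnorm(t, meanlog = p[["meanlog"]],
                                sdlog = p[["sdlog"]]),
    gengamma    = flexsurv::dgengamma(t, mu = p[["mu"]],
                                      sigma = p[["sigma"]], Q = p[["Q"]]))
  as.numeric(d)
}

#' Event-time quantile F^{-1}(p)
#'
#' Time by which a fraction `p` of the cohort has experienced the event,
#' i.e. the `t` with S(t) = 1 - p.
#'
#' @inheritParams surv_prob
#' @param p Probabilities in \[0, 1).
#' @return Times in months.
#' @export
surv_quantile <- function(model, p) {
  model <- as_parsurv(model)
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  pp <- model$params
  q <- switch(model$family,
    exponential = stats::qexp(p, rate = pp[["rate"]]),
    weibull     = stats::qweibull(p, shape = pp[["shape"]],
                                  scale = pp[["scale"]]),
    gompertz    = flexsurv::qgompertz(p, shape = pp[["shape"]],
                                      rate = pp[["rate"]]),
    loglogistic = flexsurv::qllogis(p, shape = pp[["shape"]],
                                    scale = pp[["scale"]]),
    lognormal   = stats::qlnorm(p, meanlog = pp[["meanlog"]],
                                sdlog = pp[["sdlog"]]),
    gengamma    = flexsurv::qgengamma(p, mu = pp[["mu"]],
                                      sigma = pp[["sigma"]], Q = pp[["Q"]]))
  as.numeric(q)
}

#' Median survival time
#'
#' Closed form where one exists (exponential, Weibull, log-logistic,
#' log-normal); otherwise bisection on [surv_prob()] to a relative
#' tolerance of 1e-8.
#'
#' @inheritParams surv_prob
#' @return Median time in months (`Inf` for defective distributions that
#'   never reach S = 0.5).
#' @export
median_survival <- function(model) {
  model <- as_parsurv(model)
  p <- model$params
  switch(model$family,
    exponential = log(2) / p[["rate"]],
    weibull     = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    loglogistic = p[["scale"]],
    lognormal   = exp(p[["meanlog"]]),
    {
      # gompertz / gengamma: bisection
      if (surv_prob(model, 0) < 0.5) return(0)
      hi <- 1
      while (surv_prob(model, hi) > 0.5) {
        hi <- hi * 2
        if (hi > 1e12) return(Inf)  # defective tail never drops below 0.5
      }
      lo <- hi / 2
      if (hi == 1) lo <- 0
      while ((hi - lo) > 1e-8 * max(hi, 1)) {
        mid <- (lo + hi) / 2
        if (surv_prob(model, mid) > 0.5) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    })
}
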