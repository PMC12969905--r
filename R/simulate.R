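#' Simulate right-censored individual patient data
#'
#' Event times are drawn from a parametric survival model by
#' inverse-CDF sampling; censoring is either absent, administrative at a
#' fixed time, or uniform on (0, U).
#'
#' @param model A [parametric_survival()] model (the ground truth).
#' @param n Number of subjects.
#' @param censoring `"none"`, `"administrative"` or `"uniform"`.
#' @param cens_time Administrative censoring time (months).
#' @param cens_max Upper bound of uniform censoring (months).
#' @param seed Optional integer seed.
#' @return Data frame with columns `time` and `event`.
#' @export
simulate_ipd <- function(model, n, censoring = c("none", "administrative",
                                                 "uniform"),
                         cens_time = NULL, cens_max = NULL, seed = NULL) {
  model <- as_parsurv(model)
  censoring <- match.arg(censoring)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  t_event <- surv_quantile(model, stats::runif(n))
  out <- switch(censoring,
    none = data.frame(time = t_event, event = 1L),
    administrative = {
      stopifnot(!is.null(cens_time), cens_time > 0)
      data.frame(time = pmin(t_event, cens_time),
                 event = as.integer(t_event <= cens_time))
    },
    uniform = {
      stopifnot(!is.null(cens_max), cens_max > 0)
      c_t <- stats::runif(n, 0, cens_max)
      data.frame(time = pmin(t_event, c_t),
                 event = as.integer(t_event <= c_t))
    })
  out
}

#' Digitize a KM curve and build its number-at-risk table
#'
#' Emulates the coordinates a plot-digitization tool would extract from
#' a published figure: the KM estimate sampled on a regular time grid
#' (optionally with uniform ordinate jitter of amplitude `jitter`,
#' monotonized afterwards so the result is a valid survival curve) and
#' exact at-risk counts at the requested times.
#'
#' @param ipd IPD data frame (`time`, `event`).
#' @param grid_step Grid spacing in months.
#' @param risk_times Times at which to tabulate the number at risk.
#' @param jitter Uniform ordinate jitter amplitude (0 = lossless).
#' @param seed Optional seed for the jitter.
#' @return List with `curve` (data frame `time`, `survival`, first row
#'   (0, 1)) and `risk` (data frame `time`, `n_risk`).
#' @export
make_digitized <- function(ipd, grid_step, risk_times, jitter = 0,
                           seed = NULL) {
  ipd <- validate_ipd(ipd)
  if (!nrow(ipd)) stop("empty IPD")
  if (!is.null(seed)) set.seed(seed)
  km <- km_estimate(ipd)
  fn <- km_step_fun(km)
  grid <- seq(0, max(ipd$time), by = grid_step)
  if (max(grid) < max(ipd$time)) grid <- c(grid, max(ipd$time))
  s <- fn(grid)
  if (jitter > 0) {
    s <- s + stats::runif(length(s), -jitter, jitter)
    s[1] <- 1
    s <- cummin(pmin(pmax(s, 0), 1))  # keep a valid non-increasing curve
  }
  curve <- data.frame(time = grid, survival = s)
  risk <- data.frame(time = risk_times,
                     n_risk = vapply(risk_times,
                                     function(tt) sum(ipd$time >= tt),
                                     numeric(1)))
  list(curve = curve, risk = risk)
}

#' Complete synthetic two-arm study with known ground truth
#'
#' Emulates the structure of the pivotal second-line trial this model
#' rests on: 411 subjects in the intervention arm and 416 in the
#' comparator, overall and progression-free survival drawn from the
#' base-case parametric models (log-normal for the intervention,
#' log-logistic for the comparator), administrative censoring at 43
#' months of follow-up, digitized curves on a monthly grid and quarterly
#' number-at-risk tables. Within a subject, the OS and PFS uniforms are
#' coupled through a Gaussian copula (`rho`, default 0.7), so PFS <= OS
#' holds approximately; `strict = TRUE` additionally forces
#' PFS = min(PFS, OS) per subject. Both modes are useful for exercising
#' the membership clamping rule.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n Arm sizes, named `lp` and `chemo`.
#' @param followup_months Administrative censoring time.
#' @param rho Gaussian-copula correlation between OS and PFS.
#' @param strict Force PFS <= OS per subject.
#' @return List with `ipd` (per arm, `os` and `pfs` data frames),
#'   `digitized` (per arm and endpoint, `curve` + `risk`), `config`
#'   (the base-case [base_case_config()]) and `truth` (the generating
#'   `parsurv` models).
#' @export
trial_like_fixture <- function(seed = 1L, n = c(lp = 411, chemo = 416),
                               followup_months = 43, rho = 0.7,
                               strict = FALSE) {
  set.seed(seed)
  cfg <- base_case_config()
  truth <- list(
    lp = list(os = as_parsurv(cfg$strategies$lp$os),
              pfs = as_parsurv(cfg$strategies$lp$pfs)),
    chemo = list(os = as_parsurv(cfg$strategies$chemo$os),
                 pfs = as_parsurv(cfg$strategies$chemo$pfs)))
  ipd <- list()
  digitized <- list()
  for (arm in names(truth)) {
    m <- n[[arm]]
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    t_os <- surv_quantile(truth[[arm]]$os, stats::pnorm(z1))
    t_pfs <- surv_quantile(truth[[arm]]$pfs, stats::pnorm(z2))
    if (strict) t_pfs <- pmin(t_pfs, t_os)
    arm_ipd <- list(
      os = data.frame(time = pmin(t_os, followup_months),
                      event = as.integer(t_os <= followup_months)),
      pfs = data.frame(time = pmin(t_pfs, followup_months),
                       event = as.integer(t_pfs <= followup_months)))
    ipd[[arm]] <- arm_ipd
    digitized[[arm]] <- lapply(arm_ipd, make_digitized, grid_step = 1,
                               risk_times = seq(0, followup_months, by = 3))
  }
  list(ipd = ipd, digitized = digitized, config = cfg, truth = truth,
       seed = seed)
}

#' Write IPD, digitized curves and risk tables as delimited text
#'
#' The same two-column formats the reconstruction and fitting paths
#' consume: IPD as `time,event,arm`; curves as `time,survival`; risk
#' tables as `time,n_risk`.
#'
#' @param fixture Output of [trial_like_fixture()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in names(fixture$ipd)) {
    for (ep in names(fixture$ipd[[arm]])) {
      ip <- cbind(fixture$ipd[[arm]][[ep]], arm = arm)
      utils::write.csv(ip, file.path(dir,
        paste0("ipd_", arm, "_", ep, ".csv")), row.names = FALSE)
      dg <- fixture$digitized[[arm]][[ep]]
      utils::write.csv(dg$curve, file.path(dir,
        paste0("curve_", arm, "_", ep, ".csv")), row.names = FALSE)
      utils::write.csv(dg$risk, file.path(dir,
        paste0("risk_", arm, "_", ep, ".csv")), row.names = FALSE)
    }
  }
  write_model_config(fixture$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
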