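#' Kaplan-Meier estimate from individual patient data
#'
#' Product-limit estimate via [survival::survfit()].
#'
#' @param ipd Data frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @return A `km_curve` data frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor` and `survival`, one row per distinct observed
#'   time (plus an implicit S(0) = 1 handled by [km_step_fun()]).
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  if (!nrow(ipd)) stop("empty IPD")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Step-function evaluator for a KM curve or digitized curve
#'
#' @param curve A `km_curve` or any data frame with `time` and `survival`.
#' @return A function S(t), right-continuous, with S(t) = 1 before the
#'   first tabulated time.
#' @export
km_step_fun <- function(curve) {
  stats::stepfun(curve$time, c(1, curve$survival), right = FALSE)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Implements the iterative reconstruction algorithm that allocates event
#' and censoring counts within each number-at-risk interval so that the
#' re-estimated Kaplan-Meier curve matches the digitized survival
#' ordinates and the at-risk counts match the published risk table.
#' Censoring within an interval is assumed uniformly distributed (the
#' standard assumption of this class of algorithms). If the total event
#' count is known, the final interval's censoring is calibrated to it.
#'
#' @param curve Data frame with columns `time` (months, strictly
#'   increasing, starting at or near 0) and `survival` (non-increasing,
#'   in \[0, 1\], starting at or near 1). A (0, 1) point is prepended if
#'   missing.
#' @param risk Data frame with columns `time` and `n_risk`
#'   (non-increasing counts).
#' @param total_events Optional known total number of events.
#' @return A list with `ipd` (data frame `time`, `event`) and `report`
#'   (list with `rmse`, `max_abs_dev`, `n_events`, `n_censored`): the
#'   root-mean-square and maximum absolute deviation between the input
#'   ordinates and the KM curve re-estimated from the reconstruction.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  t.S <- as.numeric(curve$time)
  S <- as.numeric(curve$survival)
  if (is.unsorted(t.S, strictly = TRUE)) {
    stop("validation error: digitized times must be strictly increasing")
  }
  if (any(S < -1e-9) || any(S > 1 + 1e-9)) {
    stop("validation error: survival ordinates outside [0, 1]")
  }
  if (any(diff(S) > 1e-9)) {
    stop("validation error: survival ordinates must be non-increasing")
  }
  S <- pmin(pmax(S, 0), 1)
  t.risk <- as.numeric(risk$time)
  n.risk <- as.numeric(risk$n_risk)
  if (any(diff(n.risk) > 0)) {
    stop("validation error: at-risk counts must be non-increasing")
  }
  if (max(t.S) < max(t.risk)) {
    stop("validation error: digitized curve must cover the risk-table range")
  }
  if (t.S[1] > 0 || S[1] < 1) {
    t.S <- c(min(0, t.S[1] - 1e-9), t.S)
    S <- c(1, S)
  }

  K <- length(t.S)
  lower <- vapply(t.risk, function(tr) which(t.S >= tr - 1e-9)[1],
                  integer(1))
  keep <- !duplicated(lower)
  lower <- lower[keep]; t.risk <- t.risk[keep]; n.risk <- n.risk[keep]
  J <- length(lower)
  upper <- c(lower[-1] - 1L, K)

  n.hat <- numeric(K + 1)
  cen <- integer(K)
  d <- integer(K)
  KM.hat <- rep(1, K)
  n.censor <- numeric(J)
  cen.times <- vector("list", J)
  last.i <- rep(1L, J + 1)

  # process clicks lower[j]..upper[j] of interval j given its censor count;
  # returns the index of the last click carrying an event
  process_interval <- function(j) {
    if (n.censor[j] <= 0) {
      cen.t <- numeric(0)
      n.censor[j] <<- 0
    } else {
      end.t <- if (j < J) t.risk[j + 1] else t.S[K]
      cen.t <- t.risk[j] + seq_len(n.censor[j]) *
        (end.t - t.risk[j]) / (n.censor[j] + 1)
    }
    idx <- lower[j]:upper[j]
    cen[idx] <<- 0L
    if (length(cen.t)) {
      bin <- findInterval(cen.t, t.S[idx])
      bin <- pmin(pmax(bin, 1L), length(idx))
      tb <- tabulate(bin, nbins = length(idx))
      cen[idx] <<- tb
    }
    cen.times[[j]] <<- cen.t
    n.hat[lower[j]] <<- n.risk[j]
    last <- last.i[j]
    for (k in idx) {
      if (j == 1 && k == lower[1]) {
        d[k] <<- 0L
        KM.hat[k] <<- 1
      } else {
        if (n.hat[k] > 0) {
          d[k] <<- as.integer(round(n.hat[k] * (1 - S[k] / KM.hat[last])))
          d[k] <<- max(0L, min(d[k], as.integer(n.hat[k])))
          KM.hat[k] <<- KM.hat[last] * (1 - d[k] / n.hat[k])
        } else {
          d[k] <<- 0L
          KM.hat[k] <<- KM.hat[last]
        }
      }
      n.hat[k + 1] <<- max(n.hat[k] - d[k] - cen[k], 0)
      if (d[k] != 0) last <- k
    }
    last
  }

  for (j in seq_len(J)) {
    if (j < J) {
      n.censor[j] <- round(n.risk[j] * S[lower[j + 1]] / S[lower[j]]) -
        n.risk[j + 1]
      if (!is.finite(n.censor[j])) n.censor[j] <- 0
    } else {
      # last interval: extrapolate the earlier censoring rate
      n.censor[J] <- if (J > 1 && t.risk[J] > t.risk[1]) {
        min(round(sum(n.censor[seq_len(J - 1)]) *
                    (t.S[K] - t.risk[J]) / (t.risk[J] - t.risk[1])),
            n.risk[J])
      } else 0
      if (!is.finite(n.censor[J]) || n.censor[J] < 0) n.censor[J] <- 0
    }
    iter <- 0
    repeat {
      last <- process_interval(j)
      iter <- iter + 1
      if (j == J || iter > 200) break
      gap <- n.hat[lower[j + 1]] - n.risk[j + 1]
      if (gap == 0) break
      if (gap < 0 && n.censor[j] <= 0) break
      n.censor[j] <- n.censor[j] + gap
    }
    if (j < J && n.hat[lower[j + 1]] < n.risk[j + 1]) {
      n.risk[j + 1] <- n.hat[lower[j + 1]]
    }
    last.i[j + 1] <- last
  }

  # calibrate the final interval to a known total event count
  if (!is.null(total_events) && !is.na(total_events)) {
    target <- total_events - sum(d[seq_len(lower[J] - 1)])
    iter <- 0
    while (sum(d[lower[J]:upper[J]]) != target && iter < 500) {
      gap <- sum(d[lower[J]:upper[J]]) - target
      n.censor[J] <- max(n.censor[J] + gap, 0)
      process_interval(J)
      iter <- iter + 1
      if (n.censor[J] == 0 && sum(d[lower[J]:upper[J]]) < target) break
    }
  }

  ev_times <- rep(t.S[d > 0], d[d > 0])
  cen_t_all <- unlist(cen.times)
  # subjects never accounted for are administratively censored at the end
  leftover <- round(n.hat[K + 1])
  if (leftover > 0) cen_t_all <- c(cen_t_all, rep(t.S[K], leftover))
  ipd <- data.frame(
    time = c(ev_times, cen_t_all),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cen_t_all))))
  ipd <- ipd[order(ipd$time, -ipd$event), , drop = FALSE]
  rownames(ipd) <- NULL

  # reconstruction-quality report against the digitized ordinates
  if (nrow(ipd)) {
    Shat <- km_step_fun(km_estimate(ipd))(t.S)
  } else {
    Shat <- rep(1, length(t.S))
  }
  dev <- Shat - S
  report <- list(rmse = sqrt(mean(dev^2)), max_abs_dev = max(abs(dev)),
                 n_events = sum(ipd$event == 1),
                 n_censored = sum(ipd$event == 0))
  list(ipd = ipd, report = report)
}

#' Hybrid KM / parametric survival curve
#'
#' Within-trial survival follows the (digitized or estimated) KM curve up
#' to `cut_time`; beyond it the fitted parametric model continues the
#' curve as a conditionally rescaled tail,
#' S(t) = KM(cut) * S_param(t) / S_param(cut), which is continuous at the
#' join by construction. `cut_time = 0` returns the pure parametric curve.
#'
#' @param curve A `km_curve`, a digitized data frame (`time`, `survival`),
#'   or IPD (`time`, `event`) from which a KM curve is first estimated.
#' @param tail_model A [parametric_survival()] model.
#' @param cut_time Join time in months (within the KM support).
#' @return A vectorized survival function over \[0, Inf).
#' @export
hybrid_survival <- function(curve, tail_model, cut_time) {
  tail_model <- as_parsurv(tail_model)
  if (cut_time < 0) stop("cut_time must be >= 0")
  if (cut_time == 0) {
    return(function(t) surv_prob(tail_model, t))
  }
  if (!is.null(curve$event) && is.null(curve$survival)) {
    curve <- km_estimate(curve)
  }
  if (cut_time > max(curve$time)) {
    stop("cut_time beyond the KM support")
  }
  km <- km_step_fun(curve)
  s_cut <- km(cut_time)
  p_cut <- surv_prob(tail_model, cut_time)
  if (s_cut <= 0) {
    stop("degenerate-tail error: KM(cut_time) = 0, no tail to extrapolate")
  }
  function(t) {
    t <- as.numeric(t)
    out <- numeric(length(t))
    inl <- t <= cut_time
    if (any(inl)) out[inl] <- km(t[inl])
    if (any(!inl)) {
      out[!inl] <- s_cut * surv_prob(tail_model, t[!inl]) / p_cut
    }
    pmin(pmax(out, 0), 1)
  }
}

#' Default hybrid cut time from a risk table
#'
#' The last risk-table time at which at least `min_frac` of the initial
#' cohort remains at risk.
#'
#' @param risk Data frame with `time` and `n_risk`.
#' @param min_frac Minimum fraction of the initial count (default 0.10).
#' @return Time in months.
#' @export
default_cut_time <- function(risk, min_frac = 0.10) {
  ok <- risk$n_risk >= min_frac * risk$n_risk[1]
  if (!any(ok)) return(risk$time[1])
  max(risk$time[ok])
}
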