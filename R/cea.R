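#' Incremental cost-effectiveness ratio
#'
#' Full-precision deltas are used throughout; rounding is display-only.
#' Negative-ratio quadrants are labelled rather than reported as a bare
#' ratio: an intervention that is cheaper and more effective is
#' "dominant", one that is costlier and less effective is "dominated".
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_effect Incremental effect.
#' @return List with `value` (NA when the ratio is not meaningful) and
#'   `label` (one of "icer", "dominant", "dominated", "undefined").
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    return(list(value = NA_real_, label = "undefined"))
  }
  if (delta_effect > 0 && delta_cost < 0) {
    return(list(value = NA_real_, label = "dominant"))
  }
  if (delta_effect < 0 && delta_cost > 0) {
    return(list(value = NA_real_, label = "dominated"))
  }
  list(value = delta_cost / delta_effect, label = "icer")
}

#' Incremental net monetary benefit
#'
#' @inheritParams icer
#' @param wtp Willingness-to-pay threshold per unit of effect.
#' @return `wtp * delta_effect - delta_cost`.
#' @export
inmb <- function(delta_cost, delta_effect, wtp) {
  wtp * delta_effect - delta_cost
}

#' Pairwise cost-effectiveness summary for two strategies
#'
#' @param summary_int,summary_comp One-row summaries from
#'   [summarize_trace()] for the intervention and comparator.
#' @param wtp Willingness-to-pay threshold.
#' @param effect Effect measure: `"qaly"` or `"ly"`.
#' @return A `cea_result` list: per-strategy cost/effect, deltas, ICER
#'   (value + dominance label) and INMB.
#' @export
cea_result <- function(summary_int, summary_comp, wtp, effect = "qaly") {
  effect <- match.arg(effect, c("qaly", "ly"))
  dc <- summary_int$cost - summary_comp$cost
  de <- summary_int[[effect]] - summary_comp[[effect]]
  ic <- icer(dc, de)
  structure(list(
    intervention = summary_int$strategy, comparator = summary_comp$strategy,
    effect_measure = effect, wtp = wtp,
    cost_int = summary_int$cost, cost_comp = summary_comp$cost,
    effect_int = summary_int[[effect]], effect_comp = summary_comp[[effect]],
    delta_cost = dc, delta_effect = de,
    icer = ic$value, icer_label = ic$label,
    inmb = inmb(dc, de, wtp)), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> ", x$intervention, " vs ", x$comparator,
      " (", toupper(x$effect_measure), ")\n", sep = "")
  cat(sprintf("  delta cost   : %s\n", format(round(x$delta_cost),
                                              big.mark = ",")))
  cat(sprintf("  delta effect : %.4f\n", x$delta_effect))
  if (x$icer_label == "icer") {
    cat(sprintf("  ICER         : %s per %s\n",
                format(round(x$icer), big.mark = ","),
                toupper(x$effect_measure)))
  } else {
    cat("  ICER         : ", x$icer_label, "\n", sep = "")
  }
  cat(sprintf("  INMB @ WTP %s : %s\n", format(x$wtp, big.mark = ","),
              format(round(x$inmb), big.mark = ",")))
  invisible(x)
}

check_psa_draws <- function(draws) {
  need <- c("cost_int", "cost_comp")
  if (!all(need %in% names(draws))) {
    stop("draws must have columns cost_int/cost_comp and matching effects")
  }
  draws
}

psa_effect_cols <- function(draws, effect) {
  effect <- match.arg(effect, c("qaly", "ly"))
  cols <- paste0(effect, c("_int", "_comp"))
  if (!all(cols %in% names(draws))) {
    # fall back to generic eff_int/eff_comp columns
    cols <- c("eff_int", "eff_comp")
  }
  if (!all(cols %in% names(draws))) stop("no effect columns found in draws")
  cols
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the intervention's net monetary benefit is at least the comparator's
#' (ties count for the intervention).
#'
#' @param draws PSA draws: a data frame with columns `cost_int`,
#'   `cost_comp` and effect columns (`qaly_int`/`qaly_comp`,
#'   `ly_int`/`ly_comp`, or `eff_int`/`eff_comp`), e.g. from [run_psa()].
#' @param wtp_grid Numeric vector of thresholds.
#' @param effect Effect measure used to compute NMB.
#' @return Data frame with columns `wtp` and `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid, effect = "qaly") {
  draws <- check_psa_draws(draws)
  if (!nrow(draws)) stop("empty draws")
  ec <- psa_effect_cols(draws, effect)
  de <- draws[[ec[1]]] - draws[[ec[2]]]
  dc <- draws$cost_int - draws$cost_comp
  prob <- vapply(wtp_grid,
                 function(w) mean(w * de - dc >= 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Per-person expected value of perfect information
#'
#' Mean over draws of the best strategy's NMB, minus the best strategy's
#' mean NMB; non-negative by construction.
#'
#' @inheritParams ceac
#' @param wtp Willingness-to-pay threshold.
#' @return EVPI in currency units per person.
#' @export
evpi <- function(draws, wtp, effect = "qaly") {
  draws <- check_psa_draws(draws)
  if (nrow(draws) < 2) stop("need at least 2 draws for EVPI")
  ec <- psa_effect_cols(draws, effect)
  nmb_int <- wtp * draws[[ec[1]]] - draws$cost_int
  nmb_comp <- wtp * draws[[ec[2]]] - draws$cost_comp
  mean(pmax(nmb_int, nmb_comp)) - max(mean(nmb_int), mean(nmb_comp))
}

#' Round half-up to integer currency (display only)
#'
#' @param x Numeric.
#' @return `x` rounded half-up to the nearest integer.
#' @export
round_currency <- function(x) {
  # pre-round to microdollars so binary-float noise (e.g. 0.5 stored as
  # 0.4999...) cannot tip a half-cent case the wrong way
  x <- round(x, 6)
  sign(x) * floor(abs(x) + 0.5)
}
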