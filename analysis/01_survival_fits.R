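#!/usr/bin/env Rscript
# Survival-curve workflow on a synthetic two-arm study with known truth.
#
# The published trial releases no individual patient data, so the fitting
# path is exercised end-to-end on the trial-like fixture: simulate both
# arms (411/416 subjects, administrative censoring at 43 months of
# follow-up), digitize their KM curves to a monthly grid with quarterly
# number-at-risk tables, reconstruct pseudo-IPD from the digitized
# coordinates, and refit the six parametric families to both the true and
# the reconstructed data. What this shows: the generating family is
# recovered near the top of the information-criterion ranking, and the
# reconstruction is faithful enough that fits on pseudo-IPD agree with
# fits on the true IPD.

library(psmcea)

dir.create("results", showWarnings = FALSE)
fx <- trial_like_fixture(seed = 2025)

rows <- list()
for (arm in names(fx$ipd)) {
  for (ep in names(fx$ipd[[arm]])) {
    truth <- fx$truth[[arm]][[ep]]
    ipd <- fx$ipd[[arm]][[ep]]

    dg <- fx$digitized[[arm]][[ep]]
    rec <- reconstruct_ipd(dg$curve, dg$risk,
                           total_events = sum(ipd$event))

    for (src in c("true_ipd", "reconstructed_ipd")) {
      dat <- if (src == "true_ipd") ipd else rec$ipd
      tab <- fit_table(rank_models(dat))
      rows[[length(rows) + 1]] <- cbind(
        arm = arm, endpoint = ep, source = src,
        truth_family = truth$family, rank = seq_len(nrow(tab)),
        reconstruction_rmse = rec$report$rmse, tab)
    }
    cat(sprintf("%s %s: reconstruction rmse %.4f (max dev %.4f)\n",
                arm, toupper(ep), rec$report$rmse,
                rec$report$max_abs_dev))
  }
}
fits <- do.call(rbind, rows)
write.csv(fits, "results/survival_fits.csv", row.names = FALSE)

top <- fits[fits$rank == 1, c("arm", "endpoint", "source", "truth_family",
                              "family", "aic")]
cat("\nBest-fit family per arm/endpoint (vs generating truth):\n")
print(top, row.names = FALSE)
cat("\nWrote results/survival_fits.csv\n")
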