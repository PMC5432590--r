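#!/usr/bin/env Rscript
# Fits the per-treatment sigmoidal vulnerability curves to the synthetic
# study data, derives PLC50 / Psi12 / Psi88 / midpoint slope with bootstrap
# intervals, and runs the linearized treatment comparison. Writes
# results/vc_parameters.csv and results/vc_comparison.csv.

suppressPackageStartupMessages(library(vinehydro))

obs <- read_plc_observations("results/data/vc_observations.csv")
truth <- jsonlite::read_json("results/data/ground_truth.json")

fits <- lapply(split(obs, obs$treatment), fit_vc, n_bootstrap = 500,
               seed = 42)
tab <- do.call(rbind, lapply(names(fits), function(tr) {
  f <- fits[[tr]]
  data.frame(treatment = tr, plc50 = f$plc50,
             plc50_lo = f$ci[1, "plc50"], plc50_hi = f$ci[2, "plc50"],
             alpha = f$alpha, slope_at_p50 = f$slope_at_p50,
             psi12 = f$psi12, psi88 = f$psi88, n = f$n_obs,
             plc50_true = truth$vc[[tr]]$plc50)
}))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/vc_parameters.csv", row.names = FALSE)

cat("Vulnerability-curve fits (bootstrap 95% CI):\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %s: PLC50 %.3f [%.3f, %.3f] MPa (truth %.2f), slope %.1f %%/MPa\n",
              tab$treatment[i], tab$plc50[i], tab$plc50_lo[i], tab$plc50_hi[i],
              tab$plc50_true[i], tab$slope_at_p50[i]))
}

cmp <- compare_treatments(obs)
print(cmp)
cmp_tab <- cmp$coefficients
cmp_tab$joint_F <- cmp$joint_test$F
cmp_tab$joint_p <- cmp$joint_test$p_value
cmp_tab$interaction_p <- cmp$interaction_test$p_value
write.csv(cmp_tab, "results/vc_comparison.csv", row.names = FALSE)
cat("The joint test contrasts the three treatments' linearized curves;\n")
cat("with distinct generating PLC50s it should reject, and the back-solved\n")
cat("per-treatment parameters should track the nonlinear fits above.\n")
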