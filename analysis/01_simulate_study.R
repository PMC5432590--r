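#!/usr/bin/env Rscript
# Builds the full synthetic study: per-treatment vulnerability-curve
# observations, pressure-volume dehydration curves, petiole vessel
# populations, and gas-exchange daily courses, all from the treatment
# presets (WW / TD / SD) with a fixed seed. Datasets are written as plain
# CSV under results/data/ with their generating parameters alongside, so
# every later stage can be checked against known truth.

suppressPackageStartupMessages(library(vinehydro))

seed <- 20260
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

treatments <- c("WW", "TD", "SD")
truth <- list(seed = seed)

## vulnerability curves: 36 shoots per treatment, sigma = 5 PLC
vc <- do.call(rbind, lapply(seq_along(treatments), function(i) {
  p <- treatment_preset(treatments[i])$vc
  simulate_vc(p$alpha, p$plc50, n = 36, noise_sd = 5, seed = seed + i,
              treatment = treatments[i])
}))
write.csv(vc, file.path(out, "vc_observations.csv"), row.names = FALSE)
truth$vc <- lapply(setNames(treatments, treatments),
                   function(tr) treatment_preset(tr)$vc)

## pressure-volume curves: 9 leaves per treatment, 15 points, 1% noise
pv_long <- do.call(rbind, unlist(lapply(seq_along(treatments), function(i) {
  p <- treatment_preset(treatments[i])$pv
  lapply(1:9, function(j) {
    cv <- simulate_pv(p$pi100, p$epsilon, apoplastic_fraction = 0.05,
                      n = 15, noise_rel = 0.01, seed = seed + 100 * i + j,
                      leaf_id = sprintf("%s_L%02d", treatments[i], j),
                      treatment = treatments[i])
    data.frame(leaf_id = cv$leaf_id, treatment = cv$treatment,
               cv$observations, turgid_weight = cv$turgid_weight,
               dry_weight = cv$dry_weight)
  })
}), recursive = FALSE))
write.csv(pv_long, file.path(out, "pv_curves.csv"), row.names = FALSE)
truth$pv <- lapply(setNames(treatments, treatments),
                   function(tr) treatment_preset(tr)$pv)

## petiole anatomy: 7 half-sections per treatment
ves_list <- list(); sec_list <- list()
for (i in seq_along(treatments)) {
  p <- treatment_preset(treatments[i])$vessels
  for (j in 1:7) {
    id <- sprintf("%s_P%02d", treatments[i], j)
    v <- simulate_vessels(mean_diameter = p$mean_diameter, log_sd = p$log_sd,
                          n = round(p$n / 2), seed = seed + 1000 * i + j)
    ves_list[[id]] <- data.frame(section_id = id, v)
    sec_list[[id]] <- data.frame(section_id = id, treatment = treatments[i],
                                 petiole_area_mm2 = p$petiole_area,
                                 leaf_area_cm2 = p$leaf_area,
                                 n_bundles = 25, half_section = TRUE)
  }
}
write.csv(do.call(rbind, ves_list), file.path(out, "vessels.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, sec_list), file.path(out, "sections.csv"),
          row.names = FALSE)

## gas-exchange: declining k_leaf courses; the SD treatment keeps k_leaf
## higher under equal tension (wetter decline midpoint for WW/TD)
decline <- list(WW = -0.45, TD = -0.50, SD = -0.65)
course <- do.call(rbind, lapply(seq_along(treatments), function(i) {
  simulate_decline_study(k_leaf_max = 32, alpha_k = 6,
                         psi50_k = decline[[treatments[i]]],
                         psi_range = c(-1.3, -0.05), n = 120,
                         noise_rel = 0.04, seed = seed + 5000 + i,
                         treatment = treatments[i])
}))
write.csv(course, file.path(out, "gas_exchange.csv"), row.names = FALSE)
truth$kleaf_decline_midpoints <- decline

jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat("Synthetic study written to", out, "\n")
cat("  VC:", nrow(vc), "observations;  PV:", length(unique(pv_long$leaf_id)),
    "leaves;  anatomy:", length(sec_list), "sections;  course:",
    nrow(course), "records\n")
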