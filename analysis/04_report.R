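#!/usr/bin/env Rscript
# Step 4: collate the study summary.
#
# Reads the fit and metrics tables written by steps 2-3 and assembles the
# headline numbers: per-environment water-bridge energies with their
# shoulder-plateau forces, the pH5:pH3 percentage ratio, conformation sizes
# and the viscosity ratios.  Written to results/summary.json.

library(chitinsmfs)

fit <- read.delim("results/fit/fit_report.tsv")
cmp <- read.delim("results/fit/comparison.tsv")
rg <- read.delim("results/metrics/rg_series.tsv")
hb <- read.delim("results/metrics/hbonds.tsv")
visc <- tryCatch(read.delim("results/metrics/viscosity.tsv"),
                 error = function(e) NULL)

plateau <- vapply(seq_len(nrow(fit)), function(i) {
  transition_force(two_state_parameters(delta_g = fit$delta_g_kbt[i],
                                        unit_length_forced = fit$l_f_nm[i]))
}, numeric(1))

summary <- list(
  elasticity = data.frame(
    environment = fit$environment,
    delta_g_kbt = fit$delta_g_kbt,
    delta_g_kjmol = fit$delta_g_kjmol,
    plateau_force_pN = round(plateau)),
  comparisons = cmp,
  rg_mean_A = vapply(split(rg$rg_A, rg$condition), mean, numeric(1)),
  hbond_inter_intra = vapply(split(hb, hb$condition), function(d) {
    if (mean(d$intra) > 0) mean(d$inter) / mean(d$intra) else Inf
  }, numeric(1)))
if (!is.null(visc)) {
  summary$normalized_eta <- stats::setNames(visc$normalized_eta,
                                            visc$condition)
}

jsonlite::write_json(summary, "results/summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "rows")

message("study summary (results/summary.json):")
message("  water-bridge energies and plateau forces:")
for (i in seq_len(nrow(summary$elasticity))) {
  e <- summary$elasticity[i, ]
  message(sprintf("    %-5s %.2f kJ/(mol.unit), plateau ~%d pN",
                  e$environment, e$delta_g_kjmol, e$plateau_force_pN))
}
row <- cmp[cmp$env_a %in% c("pH3", "pH5") & cmp$env_b %in% c("pH3", "pH5"), ]
if (nrow(row) == 1) {
  message(sprintf("  %s:%s energy ratio = %d%%",
                  row$env_a, row$env_b, row$ratio_percent))
}
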