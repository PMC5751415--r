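#!/usr/bin/env Rscript
# Assign assay-pH (7.40) charge states to each analogue from its
# per-site pKa values, enumerate the plausible microstates within the
# predictor's ~1 pKa-unit uncertainty band, and resolve the three
# explored charge-state combinations into per-site assignments.

library(cgbsa)

dir.create("results", showWarnings = FALSE)

panel <- balanol_panel()

cat("Default charge states at pH 7.40 (theta = 0.75):\n")
defaults <- lapply(panel, default_state, ph = 7.40, theta = 0.75)
for (lig in names(defaults)) {
  st <- defaults[[lig]]
  ion <- names(st$assignment[st$assignment == "ionised"])
  cat(sprintf("  %-3s state %s, net %+d e, ionised: %s\n", lig,
              st$state_label, st$net_charge, paste(ion, collapse = ", ")))
}
write.csv(charge_states_to_table(defaults), "results/default_states.csv",
          row.names = FALSE, quote = FALSE)

cat("\nMicrostates within 1.0 pKa unit of the pH:\n")
enums <- lapply(panel, enumerate_states, ph = 7.40, margin = 1.0)
for (lig in names(enums)) {
  labels <- vapply(enums[[lig]], `[[`, character(1), "state_label")
  cat(sprintf("  %-3s %2d states (labelled: %s)\n", lig, length(enums[[lig]]),
              paste(sort(unique(labels[!is.na(labels)])), collapse = " ")))
}

combos <- balanol_combinations()
rows <- do.call(rbind, lapply(names(combos), function(cid) {
  states <- resolve_combination(panel, combos[[cid]])
  df <- charge_states_to_table(states)
  cbind(combination = cid, df)
}))
write.csv(rows, "results/state_combinations.csv", row.names = FALSE,
          quote = FALSE)
cat("\nWritten: results/default_states.csv, results/state_combinations.csv\n")
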