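#!/usr/bin/env Rscript
# Desk-scale validation of the scoring terms against closed forms:
# the analytic Born sphere, isolated-sphere LCPO areas, the bare
# Coulomb pair, the separation limit of the binding energy, and the
# exact cancellation of bonded terms under single-trajectory
# extraction.

library(cgbsa)

dir.create("results", showWarnings = FALSE)

checks <- list()

born_top <- topology(
  data.frame(name = "X", charge = 1, rmin_half = 1.7, epsilon = 0,
             gb_radius = 2.09, vdw_radius = 1.7, p1 = 1, p2 = 0, p3 = 0,
             p4 = 0),
  receptor = 1, ligand = integer(0))
origin <- snapshot(matrix(0, 1, 3))
checks$born_sphere <- c(
  value = gb_energy(born_top, origin),
  expected = -(332.0636 / 2) * (1 - 1 / 78.5) / 2)

checks$lcpo_isolated <- c(value = lcpo_sasa(born_top, origin, 1.4)$total,
                          expected = 4 * pi * 3.1^2)

pair_top <- topology(
  data.frame(name = c("A", "B"), charge = c(1, -1), rmin_half = 1.7,
             epsilon = 0, gb_radius = 1.7, vdw_radius = 1.7,
             p1 = 0, p2 = 0, p3 = 0, p4 = 0),
  receptor = 1, ligand = 2)
pair_sn <- snapshot(rbind(c(0, 0, 0), c(3.320636, 0, 0)))
checks$coulomb_pair <- c(
  value = unname(nonbonded_energy(pair_top, pair_sn)["e_elec"]),
  expected = -100)

tc <- make_toy_complex(18, 5, seed = 14)
f <- make_trajectory(tc$top, tc$ref, 1, noise_sigma = 0.25, seed = 14)[[1]]
checks$bonded_cancellation <- c(
  value = abs(snapshot_delta_g(tc$top, f, include_bonded = TRUE)$dg -
                snapshot_delta_g(tc$top, f, include_bonded = FALSE)$dg),
  expected = 0)

apart <- make_toy_complex(10, 4, seed = 15, ligand_net_charge = 0,
                          pocket_charge = 0)
xyz <- apart$ref$coordinates
xyz[apart$top$ligand, 1] <- xyz[apart$top$ligand, 1] + 300
checks$separation_limit <- c(
  value = snapshot_delta_g(apart$top, snapshot(xyz))$dg,
  expected = 0)

df <- data.frame(check = names(checks),
                 value = vapply(checks, `[[`, numeric(1), "value"),
                 expected = vapply(checks, `[[`, numeric(1), "expected"))
df$abs_dev <- abs(df$value - df$expected)
write.csv(df, "results/energy_checks.csv", row.names = FALSE, quote = FALSE)
print(df, row.names = FALSE, digits = 6)
cat("\nWritten: results/energy_checks.csv\n")
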