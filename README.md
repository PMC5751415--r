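# cgbsa

Charge-state exploration and single-trajectory MM/GBSA binding-energy
scoring for kinase-inhibitor panels, built around (-)-balanol and its
fluorinated azepane analogues (1a, 1c, 1d, 1e) binding PKA and
PKC-epsilon.

Balanol carries one basic amine (N1) and five acidic groups (four
phenols, one carboxylic acid). Which sites are ionised at assay pH
decides the species that binds the ATP site, and an end-state
binding-energy estimate is only meaningful once that charge state is
right. This package implements the full desk-side workflow:

- **Kd ⇌ ΔG°**: `ΔG° = RT ln(Kd/c⁰)` at a 1 M standard state
  (R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, default T = 300 K), with
  first-order error propagation `δΔG = RT·δKd/Kd`.
- **Protonation states**: Henderson–Hasselbalch ionised fractions per
  site, threshold-based default assignment (θ = 0.75), and 2ⁿ
  microstate enumeration over sites within 1 pKa unit of the pH —
  reconstructing the catalogued states A–D and the three explored
  charge-state combinations I–III.
- **MM/GBSA scoring**: `G = E_MM + G_GB + G_SA` per snapshot with
  Amber-convention molecular mechanics, OBC-style Generalized Born
  electrostatic solvation, and LCPO surface area;
  `ΔG°_MMGBSA = G_complex − G_receptor − G_ligand` evaluated on
  coordinates from the same complex snapshot, so bonded terms cancel
  exactly (single-trajectory approximation).
- **Windows and correlation**: 10-ns non-overlapping window means ±
  SD, squared Pearson correlation r² of window means against
  experimental ΔG° across the ligand panel, range-averaged over
  40–100 ns, with seeded Monte-Carlo error bars from the Kd errors.
- **Synthetic panels**: deterministic toy receptor–ligand systems
  with prescribed affine affinities and window-scale drift, so every
  pipeline stage has a known ground truth without running MD.

## Worked example

Converting the measured panel and assigning assay-pH charge states:

```r
library(cgbsa)

dg <- affinity_to_dg_table(balanol_affinities(), temperature = 300)
subset(dg, kinase == "PKCe")
#>    ligand kinase dg_kcal_mol dg_err_kcal_mol temperature_K
#> 6       1   PKCe  -12.542000      0.04899945           300
#> 7      1a   PKCe  -10.599025      0.25101474           300
#> 8      1c   PKCe  -12.900638      0.02980800           300
#> 9      1d   PKCe   -9.552144      0.10297309           300
#> 10     1e   PKCe  -10.185799      0.14904000           300

st <- default_state(balanol_panel()[["1"]], ph = 7.40, theta = 0.75)
names(st$assignment[st$assignment == "ionised"])
#> [1] "N1"       "C6''OH"   "C15''O2H"
net_charge(st)
#> [1] -1
```

The 5S-fluorinated analogue 1c is the strongest binder
(−12.90 kcal/mol against PKC-epsilon); balanol's dominant microstate
at pH 7.40 is the zwitterion-like state C (ammonium, phenolate,
carboxylate; net −1 e). Scoring a synthetic panel end to end:

```r
res <- run_demo(seed = 1, outdir = "demo", n_receptors = 1)
res$results$R1$correlation
#> correlation series: 10 windows, range-average r^2 = 0.996 over [40, 100] ns
```

The window means track the prescribed affine affinities almost
perfectly (r² ≈ 1) because the generator's ground truth is linear by
construction — see the vignette for what that does and does not
demonstrate.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (experimental conversions, charge states,
closed-form energy validation, synthetic panel) and write their
tables under `results/`.

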