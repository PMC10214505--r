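# dualbind

Tools for the **dual-binding theory of protein–protein interaction (PPI)
stabilizers** (molecular glues): an exact ternary-complex equilibrium model,
dual-binding scoring of candidate stabilizers from MM/GBSA-style
interaction-energy tables, interface-pocket geometry analysis, and an
orchestrated in-silico stabilizer discovery pipeline. It is written for
computational chemists and structural bioinformaticians who post-process
molecular-dynamics ensembles and pocket-detection output to find and rank
PPI stabilizers.

## The model

A stabilizer S binds a receptor R and a ligand protein L with dissociation
constants K_RS and K_LS and cooperativity φ, forming the ternary complex
R·L·S. `dualbind` solves the coupled mass-action system exactly; in the
dilute limit

    [RLS] = φ [R0][L0][S_f] / ((K_RS + [S_f]) (K_LS + [S_f]))

which peaks at [S_f] = √(K_RS·K_LS) — the *hook effect*: past the optimal
dose, binary RS and LS complexes saturate and the ternary complex declines.
At the optimal dose the effective protein–protein dissociation constant is

    K_RL,eff = [R0][L0] / [RLS_opt] = (√K_RS + √K_LS)² / φ

so stabilization efficiency is governed by the *weaker* of the two
per-partner interactions, max{ΔΔG_RS, ΔΔG_LS} (with
K_D = exp(ΔΔG/RT)). That is the dual-binding principle: a good glue must
bind both partners comparably well. From it follow the package's two
decision rules: a weaker side of −5 kcal/mol is the minimum for micromolar
effective affinity at 1 µM partners (mechanism classification:
dual-binding vs allosteric candidate), and shortlisting demands a weaker
side below −15 kcal/mol with a binding balance |ΔΔG_RS − ΔΔG_LS| below
10 kcal/mol.

## Worked example

```r
library(dualbind)
library(dplyr)

# 1. How strong must a symmetric dual binder be for micromolar efficacy?
threshold_scan(seq(-1, -10, by = -0.5))
#> Minimum symmetric binding free energy: -5.00 kcal/mol (K_RL,eff <= 0.001 M)

# 2. Optimal dose for a -5/-5 kcal/mol stabilizer at 1 uM partners
p <- binding_parameters_dg(-5, -5)
tidy(optimal_dose(p, r0 = 1e-6, l0 = 1e-6))
#> # A tibble: 1 x 4
#>     s0_opt       rls_opt k_rl_eff flat
#>      <dbl>         <dbl>    <dbl> <lgl>
#> 1 0.000217 0.00000000115 0.000867 FALSE

# 3. Classify the bundled 18-complex stabilizer benchmark
known_stabilizer_energetics() |>
  classify_mechanism() |>
  count(call)
#> # A tibble: 2 x 2
#>   call                     n
#>   <chr>                <int>
#> 1 allosteric-candidate     4
#> 2 dual-binding            14
```

The optimal total dose (217 µM ≈ the geometric mean of the two 216 µM
dissociation constants plus the bound fraction) yields 1.15 nM of ternary
complex from 1 µM of each protein, i.e. K_RL,eff = 0.87 mM — just inside
the sub-millimolar range, which is why −5 kcal/mol is the threshold. In
the benchmark, the four allosteric candidates (A1-b, B2, B4, B5) are the
complexes whose stabilizer barely touches one partner.

Titration curves (`titration_curve()` + `autoplot()`), energy-grid
landscapes (`energy_grid_scan()`), SASA/BSA and interface-RMSD geometry
(`buried_surface()`, `irmsd_series()`), pocket coverage and ranking
(`ligand_coverage()`, `rank_pockets()`), and the end-to-end discovery
pipeline (`run_pipeline()`, with a deterministic mock docking adapter and
self-verifying synthetic fixtures) are covered in the vignette
(`vignettes/dual-binding-theory.Rmd`). A thin command-line wrapper ships in
`inst/scripts/dualbind.R`.

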